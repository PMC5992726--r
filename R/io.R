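# File formats: CGmap in, methylome TSV / bedGraph out, BED/GFF3 in -----

#' Read a CGmap file
#'
#' CGmap is the 8-column tab-separated per-cytosine count format produced by
#' BS-Seeker2's methylation caller: chrom, C/G nucleotide (C = forward
#' strand, G = reverse strand), 1-based position, 3-letter context class
#' (CG/CHG/CHH), dinucleotide, methylation level, methylated count, total
#' count.  Plain or gzip-compressed files are read transparently.
#'
#' @param path Path to a CGmap file (optionally `.gz`).
#' @return A `data.frame` with columns `chrom`, `nucleotide`, `position`,
#'   `context_class`, `dinucleotide`, `level`, `methylated`, `total`.
#' @export
read_cgmap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  empty <- data.frame(chrom = character(), nucleotide = character(),
                      position = integer(), context_class = character(),
                      dinucleotide = character(), level = numeric(),
                      methylated = integer(), total = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 8L))
    stop("CGmap format error: expected 8 tab-separated columns, got ",
         nf[which(nf != 8L)[1]], " at line ", which(nf != 8L)[1])
  mat <- matrix(unlist(fields), ncol = 8L, byrow = TRUE)
  out <- data.frame(
    chrom = mat[, 1], nucleotide = mat[, 2],
    position = as.integer(mat[, 3]), context_class = mat[, 4],
    dinucleotide = mat[, 5], level = as.numeric(mat[, 6]),
    methylated = as.integer(mat[, 7]), total = as.integer(mat[, 8]),
    stringsAsFactors = FALSE
  )
  badnum <- which(is.na(out$position) | is.na(out$methylated) |
                    is.na(out$total) | is.na(out$level))
  if (length(badnum))
    stop("CGmap format error: unparseable numeric field at line ", badnum[1])
  badnuc <- which(!out$nucleotide %in% c("C", "G"))
  if (length(badnuc))
    stop("CGmap format error: nucleotide column must be C or G at line ",
         badnuc[1])
  badmr <- which(out$methylated > out$total)
  if (length(badmr))
    stop("CGmap format error: methylated > total at line ", badmr[1])
  out
}

#' Write a methylome as a CGmap file
#'
#' Serializes a methylome (typically simulated) in the 8-column CGmap layout
#' so it can be fed back through [read_cgmap()].  Six-class contexts are
#' collapsed to the CGmap CG/CHG/CHH classes; the dinucleotide column holds a
#' representative dinucleotide for the class.
#'
#' @param methylome Methylome `data.frame`.
#' @param path Output path; a `.gz` suffix writes gzip-compressed output.
#' @export
write_cgmap <- function(methylome, path) {
  check_methylome(methylome)
  cls <- collapse_context(methylome$context)
  dinuc <- c(CG = "CG", CCG = "CC", CWG = "CA", CAA = "CA", CTA = "CT",
             CHH_rest = "CA", CHG = "CA", CHH = "CA")[as.character(methylome$context)]
  lev <- ifelse(methylome$total > 0,
                round(methylome$methylated / methylome$total, 6), 0)
  lines <- paste(methylome$chrom, ifelse(methylome$strand == "+", "C", "G"),
                 methylome$position, cls, dinuc, format(lev, trim = TRUE),
                 methylome$methylated, methylome$total, sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# collapse six-class contexts to CGmap CG/CHG/CHH
collapse_context <- function(context) {
  map <- c(CG = "CG", CCG = "CHG", CWG = "CHG", CAA = "CHH", CTA = "CHH",
           CHH_rest = "CHH", CHG = "CHG", CHH = "CHH")
  unname(map[as.character(context)])
}

#' Write the full per-cytosine methylome with model output
#'
#' One row per cytosine, including zero-coverage sites: chrom, position,
#' strand, context, counts, both posteriors, status call and recalibrated
#' level, with floats at 6 decimals.
#'
#' @param methylome Methylome `data.frame`.
#' @param fit A fitted [methylHMM] object aligned 1:1 with `methylome`.
#' @param path Output TSV path.
#' @export
write_methylome <- function(methylome, fit, path) {
  check_methylome(methylome)
  if (nrow(fit$gamma) != nrow(methylome))
    stop("fit and methylome are not aligned: ", nrow(fit$gamma), " vs ",
         nrow(methylome), " rows")
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  df <- data.frame(
    chrom = methylome$chrom, position = methylome$position,
    strand = methylome$strand, context = as.character(methylome$context),
    counts_methylated = methylome$methylated, counts_total = methylome$total,
    posterior_U = fmt(fit$gamma[, "U"]), posterior_M = fmt(fit$gamma[, "M"]),
    status = ifelse(is.na(fit$status), "NA", as.character(fit$status)),
    rc_level = fmt(fit$rc_level),
    stringsAsFactors = FALSE
  )
  df$context[is.na(df$context)] <- "NA"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a methylome TSV written by [write_methylome()]
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with the columns written by [write_methylome()].
#' @export
read_methylome <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  df$strand <- as.character(df$strand)
  df
}

#' Export recalibrated levels as bedGraph
#'
#' Writes one bedGraph track of the recalibrated methylation level, with
#' 0-based half-open coordinates, optionally restricted to one strand for
#' genome-browser use.
#'
#' @param methylome Methylome `data.frame`.
#' @param fit Fitted [methylHMM] object aligned with `methylome`.
#' @param path Output path.
#' @param strand `NULL` (both strands) or one of `"+"`, `"-"`.
#' @export
write_bedgraph <- function(methylome, fit, path, strand = NULL) {
  keep <- !is.na(fit$rc_level)
  if (!is.null(strand)) keep <- keep & methylome$strand == strand
  lines <- paste(methylome$chrom[keep], methylome$position[keep] - 1L,
                 methylome$position[keep],
                 sprintf("%.6f", fit$rc_level[keep]), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read an annotation file (BED or GFF3)
#'
#' Features are normalized to 1-based inclusive coordinates (BED's 0-based
#' half-open convention is converted at this boundary).
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by extension), `"BED"` or `"GFF3"`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `type`.
#' @export
read_annotation <- function(path, format = c("auto", "BED", "GFF3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)(\\.gz)?$", path, ignore.case = TRUE))
      "GFF3" else "BED"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "BED") "BED" else "GFF3"),
    error = function(e) stop("failed to parse ", format, " file ", path,
                             ": ", conditionMessage(e))
  )
  df <- as.data.frame(gr)
  type <- if ("type" %in% names(df)) as.character(df$type)
          else if ("name" %in% names(df)) as.character(df$name)
          else rep("feature", nrow(df))
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start, end = df$end,
                    strand = as.character(df$strand),
                    type = type, stringsAsFactors = FALSE)
  if (any(out$end < out$start))
    stop("feature(s) shorter than 1 bp in ", path)
  out
}
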