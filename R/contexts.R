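# Cytosine extraction and sequence-context assignment ------------------

#' Assign a sequence context to C-initial trinucleotides
#'
#' Maps the trinucleotide starting at a cytosine (read 5' to 3' on the
#' cytosine's own strand) to one of the six model contexts: any `CGx` is CG;
#' `CCG` and `CAG`/`CTG` (CWG) are the CHG subclasses; `CAA`, `CTA` and the
#' pooled remainder `CHH_rest` (CCA, CAC, CAT, CCC, CCT, CTC, CTT) are the
#' CHH subclasses.  The mapping is total over C-initial trinucleotides
#' without N.
#'
#' @param trinuc Character vector of 3-letter strings whose first base is C.
#' @return Factor with levels `c("CG","CCG","CWG","CAA","CTA","CHH_rest")`;
#'   `NA` for trinucleotides containing N or with missing downstream bases.
#' @examples
#' assign_context(c("CGA", "CTG", "CCT"))
#' @export
assign_context <- function(trinuc) {
  trinuc <- toupper(trinuc)
  bad <- !is.na(trinuc) & substr(trinuc, 1, 1) != "C" &
    !grepl("N", trinuc, fixed = TRUE)
  if (any(bad))
    stop("trinucleotide(s) not starting with C: ",
         paste(unique(trinuc[bad]), collapse = ", "))
  b2 <- substr(trinuc, 2, 2)
  b3 <- substr(trinuc, 3, 3)
  ctx <- rep(NA_character_, length(trinuc))
  ok <- !is.na(trinuc) & nchar(trinuc) == 3L &
    b2 %in% c("A", "C", "G", "T") & b3 %in% c("A", "C", "G", "T")
  ctx[ok & b2 == "G"] <- "CG"
  ctx[ok & b2 == "C" & b3 == "G"] <- "CCG"
  ctx[ok & b2 %in% c("A", "T") & b3 == "G"] <- "CWG"
  ctx[ok & b2 == "A" & b3 == "A"] <- "CAA"
  ctx[ok & b2 == "T" & b3 == "A"] <- "CTA"
  ctx[ok & is.na(ctx)] <- "CHH_rest"
  factor(ctx, levels = CONTEXTS6)
}

#' Extract all cytosines from a reference genome
#'
#' Finds every C on the forward strand and every G (a cytosine on the reverse
#' strand) in each sequence and assigns the six-class sequence context from
#' the two downstream bases on the cytosine's own strand.  Sites whose two
#' downstream bases run off the sequence end or contain N are retained with
#' `context_valid = FALSE`.
#'
#' @param genome A [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or the path to a (optionally gzipped) FASTA file.
#' @return A `data.frame` with columns `chrom`, `position` (1-based),
#'   `strand` (`+`/`-`), `context` (factor, see [assign_context()]) and
#'   `context_valid`, sorted by (chrom, position, strand with `+` first).
#' @examples
#' extract_cytosines(c(chr1 = "ACGT"))
#' @export
extract_cytosines <- function(genome) {
  seqs <- as_genome_strings(genome)
  out <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    s <- seqs[[k]]
    n <- length(s)
    res <- NULL
    fwd <- which(s == "C")
    rev <- which(s == "G")
    chrom <- names(seqs)[k]
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    b <- function(i) ifelse(i >= 1L & i <= n, s[pmax(pmin(i, n), 1L)], "N")
    tri_fwd <- if (length(fwd)) paste0("C", b(fwd + 1L), b(fwd + 2L))
               else character(0)
    tri_rev <- if (length(rev))
      paste0("C", comp[b(rev - 1L)], comp[b(rev - 2L)])
    else character(0)
    df <- data.frame(
      chrom = chrom,
      position = c(fwd, rev),
      strand = rep(c("+", "-"), c(length(fwd), length(rev))),
      trinuc = c(tri_fwd, tri_rev),
      stringsAsFactors = FALSE
    )
    out[[k]] <- df
  }
  df <- do.call(rbind, out)
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(chrom = character(), position = integer(),
                      strand = character(),
                      context = factor(character(), levels = CONTEXTS6),
                      context_valid = logical()))
  }
  df$context <- assign_context(df$trinuc)
  df$context_valid <- !is.na(df$context)
  df$trinuc <- NULL
  df <- df[order(df$chrom, df$position, df$strand == "-"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# normalize genome input to a list of uppercase character vectors (one per
# sequence); rejects non-ACGTN characters
as_genome_strings <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  if (!is.character(genome))
    stop("genome must be a DNAStringSet, named character vector, or FASTA path")
  if (is.null(names(genome)) && length(genome) > 0L)
    names(genome) <- paste0("seq", seq_along(genome))
  # FASTA headers: keep first word only
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- lapply(genome, function(x) {
    v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(v), c("A", "C", "G", "T", "N"))
    if (length(bad))
      stop("non-nucleotide character(s) in genome: ",
           paste(bad, collapse = ", "))
    v
  })
  seqs
}

#' Merge genome cytosines with CGmap read counts into a methylome
#'
#' Every genome cytosine appears exactly once in the result; sites without a
#' count record get zero counts (coverage 0).  Contexts always come from the
#' genome, never from the CGmap context columns.  Count records at positions
#' that are not cytosines in the genome (or off the chromosome end) are
#' dropped with a warning.
#'
#' @param sites Cytosine table from [extract_cytosines()].
#' @param counts CGmap records from [read_cgmap()].
#' @return A methylome `data.frame`: columns `chrom`, `position`, `strand`,
#'   `context`, `context_valid`, `methylated`, `total`, sorted by
#'   (chrom, position, strand).
#' @export
merge_counts <- function(sites, counts) {
  strand <- ifelse(counts$nucleotide == "C", "+", "-")
  key_sites <- paste(sites$chrom, sites$position, sites$strand, sep = "\r")
  key_counts <- paste(counts$chrom, counts$position, strand, sep = "\r")
  idx <- match(key_counts, key_sites)
  n_drop <- sum(is.na(idx))
  if (n_drop > 0L)
    warning(n_drop, " count record(s) at non-cytosine reference positions ",
            "were dropped")
  m <- integer(nrow(sites))
  r <- integer(nrow(sites))
  keep <- !is.na(idx)
  m[idx[keep]] <- counts$methylated[keep]
  r[idx[keep]] <- counts$total[keep]
  out <- sites
  out$methylated <- m
  out$total <- r
  out <- out[order(out$chrom, out$position, out$strand == "-"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a three-context methylome directly from CGmap records
#'
#' Genome-free fallback: when no reference FASTA is available the CGmap
#' context-class column (CG/CHG/CHH) supplies the contexts, so only
#' uncovered-site imputation within the covered positions is possible and the
#' model runs with three contexts instead of six.
#'
#' @param counts CGmap records from [read_cgmap()].
#' @return A methylome `data.frame` with a 3-level context factor.
#' @export
methylome_from_cgmap <- function(counts) {
  out <- data.frame(
    chrom = counts$chrom,
    position = counts$position,
    strand = ifelse(counts$nucleotide == "C", "+", "-"),
    context = factor(counts$context_class, levels = CONTEXTS3),
    context_valid = counts$context_class %in% CONTEXTS3,
    methylated = counts$methylated,
    total = counts$total,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$position, out$strand == "-"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# validate the methylome contract used throughout the package
check_methylome <- function(methylome) {
  need <- c("chrom", "position", "strand", "context", "context_valid",
            "methylated", "total")
  miss <- setdiff(need, names(methylome))
  if (length(miss))
    stop("methylome is missing column(s): ", paste(miss, collapse = ", "))
  if (any(methylome$methylated > methylome$total))
    stop("methylated counts exceed total counts")
  o <- order(methylome$chrom, methylome$position, methylome$strand == "-")
  if (is.unsorted(o))
    stop("methylome must be sorted by (chrom, position, strand)")
  invisible(methylome)
}
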