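# Bisulfite-sequencing-PCR (BSP) clone analysis.
#
# Clones are Sanger reads of bisulfite-converted amplicons compared against
# the untreated reference: at a CpG cytosine, C = methylated, T =
# unmethylated; at non-CpG cytosines, conversion to T is expected and the
# fraction converted is the clone's bisulfite-conversion QC. Only the
# bisulfite top strand (C-to-T) is modelled.

#' Build an amplicon reference
#'
#' @param name amplicon name.
#' @param seq reference DNA sequence (untreated), A/C/G/T.
#' @return list of class `bsp_amplicon` with `name`, `seq` and
#'   `cpg_positions` (0-based indices of each CpG's C).
#' @export
amplicon <- function(name, seq) {
  seq <- toupper(seq)
  if (!grepl("^[ACGT]+$", seq)) stop2("amplicon must be over A/C/G/T")
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  cpg <- if (m[1] == -1L) integer() else as.integer(m) - 1L
  structure(list(name = name, seq = seq, cpg_positions = cpg),
            class = "bsp_amplicon")
}

# Global alignment of a (possibly indel-containing) clone to the reference,
# bisulfite-aware: C/T and G/A are scored as matches. Returns the clone
# base at each reference position ("-" at deletions).
align_clone_to_ref <- function(ref_seq, clone_seq) {
  bases <- c("A", "C", "G", "T")
  sub <- matrix(-1, 4, 4, dimnames = list(bases, bases))
  diag(sub) <- 1
  sub["C", "T"] <- sub["T", "C"] <- 1  # bisulfite conversion
  sub["G", "A"] <- sub["A", "G"] <- 1  # bottom-strand read of the same event
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(clone_seq),
    subject = Biostrings::DNAString(ref_seq),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  out <- character(nchar(ref_seq))
  ref_i <- 0L
  for (k in seq_along(s)) {
    if (s[k] != "-") {
      ref_i <- ref_i + 1L
      out[ref_i] <- p[k]
    }
  }
  paste(out, collapse = "")
}

#' Call per-CpG methylation for one clone
#'
#' The clone is compared position-by-position with the reference (after a
#' bisulfite-aware Needleman-Wunsch alignment when lengths differ and
#' `align = TRUE`; match +1, mismatch -1, gap -2, C/T and G/A scored as
#' matches). At each CpG cytosine: C = `methylated`, T = `unmethylated`,
#' anything else (including a gap) = `ambiguous`. The conversion rate is
#' the fraction of non-CpG reference cytosines read as T; the clone passes
#' QC when it reaches `qc_threshold`.
#'
#' @param ref `bsp_amplicon` from [amplicon()].
#' @param clone_seq clone sequence.
#' @param clone_id identifier carried into the output.
#' @param qc_threshold minimum conversion rate (default 0.95).
#' @param align allow alignment of length-mismatched clones (default TRUE);
#'   with `align = FALSE` a length mismatch is an error.
#' @return list of class `bsp_clone_call`: `clone_id`, `calls` (character
#'   vector over `ref$cpg_positions`), `conversion_rate`, `passed_qc`.
#' @export
call_clone <- function(ref, clone_seq, clone_id = "clone",
                       qc_threshold = 0.95, align = TRUE) {
  stopifnot(inherits(ref, "bsp_amplicon"))
  clone_seq <- toupper(clone_seq)
  if (nchar(clone_seq) != nchar(ref$seq)) {
    if (!align) stop2("clone length (%d) differs from reference (%d)",
                      nchar(clone_seq), nchar(ref$seq))
    clone_seq <- align_clone_to_ref(ref$seq, clone_seq)
  }
  rch <- strsplit(ref$seq, "")[[1]]
  cch <- strsplit(clone_seq, "")[[1]]
  cpg <- ref$cpg_positions + 1L
  calls <- vapply(cpg, function(i) {
    switch(cch[i], C = "methylated", T = "unmethylated", "ambiguous")
  }, character(1))
  non_cpg_c <- setdiff(which(rch == "C"), cpg)
  conv <- if (length(non_cpg_c)) {
    sum(cch[non_cpg_c] == "T") / length(non_cpg_c)
  } else NA_real_
  passed <- !is.na(conv) && conv >= qc_threshold
  structure(list(clone_id = clone_id, calls = calls,
                 conversion_rate = conv, passed_qc = passed),
            class = "bsp_clone_call")
}

#' Summarize clone calls for one sample
#'
#' The sample methylation rate is `methylated / (methylated + unmethylated)`
#' over all QC-passing clones; ambiguous calls are excluded from both the
#' numerator and the denominator, as are failing clones. A warning (not an
#' error) is raised when fewer than `min_clones` clones pass — the standard
#' BSP protocol expects 10 per sample.
#'
#' @param calls list of `bsp_clone_call` objects.
#' @param sample_id,group identifiers carried into the output.
#' @param min_clones expected number of passing clones (default 10).
#' @return list of class `bsp_sample`: `sample_id`, `group`, `n_clones`
#'   (passing), `rate`, `per_site_rates`.
#' @export
sample_summary <- function(calls, sample_id = "sample", group = NA_character_,
                           min_clones = 10L) {
  pass <- Filter(function(x) isTRUE(x$passed_qc), calls)
  if (!length(pass)) stop2("sample %s: no clone passed conversion QC", sample_id)
  if (length(pass) < min_clones) {
    warning(sprintf("sample %s: only %d of %d clones passed QC (expected >= %d)",
                    sample_id, length(pass), length(calls), min_clones),
            call. = FALSE)
  }
  mat <- do.call(rbind, lapply(pass, `[[`, "calls"))
  meth <- mat == "methylated"
  unmeth <- mat == "unmethylated"
  rate <- sum(meth) / (sum(meth) + sum(unmeth))
  per_site <- colSums(meth) / (colSums(meth) + colSums(unmeth))
  structure(list(sample_id = sample_id, group = group,
                 n_clones = length(pass), rate = rate,
                 per_site_rates = per_site),
            class = "bsp_sample")
}

#' Lollipop matrix of clone calls
#'
#' @param calls list of `bsp_clone_call` objects.
#' @param passing_only keep only QC-passing clones (default TRUE).
#' @return character matrix, rows = clones, columns = CpG sites, entries
#'   `"1"` (methylated), `"0"` (unmethylated), `"?"` (ambiguous).
#' @export
clone_matrix <- function(calls, passing_only = TRUE) {
  if (passing_only) calls <- Filter(function(x) isTRUE(x$passed_qc), calls)
  mat <- do.call(rbind, lapply(calls, function(x) {
    c(methylated = "1", unmethylated = "0", ambiguous = "?")[x$calls]
  }))
  rownames(mat) <- vapply(calls, `[[`, character(1), "clone_id")
  colnames(mat) <- NULL
  mat
}

#' Compare per-sample BSP methylation rates between groups
#'
#' Two-sided Mann-Whitney test on per-sample rates; with `paired = TRUE`
#' (tumor/normal pairs in matching order) the Wilcoxon signed-rank variant
#' is used.
#'
#' @param samples list of `bsp_sample` objects (or a data.frame with
#'   columns `rate`, `group`).
#' @param paired treat samples as tumor/normal pairs in matching order.
#' @return list with `statistic` and `p`.
#' @export
compare_groups <- function(samples, paired = FALSE) {
  if (is.data.frame(samples)) {
    df <- samples
  } else {
    df <- data.frame(rate = vapply(samples, `[[`, numeric(1), "rate"),
                     group = vapply(samples, `[[`, character(1), "group"),
                     stringsAsFactors = FALSE)
  }
  tum <- df$rate[df$group == "tumor"]
  nor <- df$rate[df$group == "normal"]
  if (length(tum) < 2L || length(nor) < 2L) {
    stop2("both groups need at least 2 samples")
  }
  if (paired && length(tum) != length(nor)) {
    stop2("paired comparison requires equal group sizes")
  }
  mw_test(tum, nor, paired = paired)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a named
#' character vector.
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to a FASTA file
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}
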