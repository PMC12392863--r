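AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Hydrophobic residues rendered as the Psi symbol in consensus motifs.
# Deliberately excludes S/T/Y, which consensus notation treats as "small"
# rather than hydrophobic.
HYDROPHOBIC_DEFAULT <- c("A", "V", "L", "I", "M", "F", "W", "C")

#' Aligned repeat set
#'
#' Equal-length amino-acid sequences (gaps as `-`) forming one alignment,
#' typically the HMM match-state columns of a set of imperfect repeats.
#' This container validates only; alignment itself happens upstream.
#'
#' @param sequences character vector of aligned sequences.
#' @param label optional source label (e.g. "IR1", "FapC combined").
#' @return an object of class `repeat_alignment`.
#' @export
repeat_alignment <- function(sequences, label = NULL) {
  sequences <- toupper(as.character(sequences))
  if (!length(sequences)) stop("empty alignment", call. = FALSE)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  chars <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  bad <- setdiff(chars, c(AA20, "-"))
  if (length(bad))
    stop("illegal character(s) in alignment: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(sequences = sequences, label = label,
                 n_columns = lens[1]),
            class = "repeat_alignment")
}

#' Read an aligned FASTA into a repeat alignment
#'
#' @param path aligned FASTA file (amino acids, `-` gaps).
#' @param label optional source label.
#' @return a [repeat_alignment()].
#' @export
read_repeat_alignment <- function(path, label = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  repeat_alignment(as.character(ss), label = label)
}

#' Position frequency matrix of an alignment
#'
#' Per-column residue frequencies computed over non-gap residues only
#' (gaps are excluded from the 20-letter simplex and tracked separately as
#' a per-column gap fraction — the usual sequence-logo convention).
#' Optional Laplace smoothing adds `pseudocount` to every residue count.
#'
#' @param aln a [repeat_alignment()] (or character vector of aligned
#'   sequences).
#' @param pseudocount added to each residue count before normalization
#'   (default 0).
#' @return an object of class `pfm` with `freq` (20 x n_columns matrix,
#'   rows named by residue; columns sum to 1 where any residue is
#'   present), `gap_frac`, `n_seq` and `n_columns`.
#' @export
build_pfm <- function(aln, pseudocount = 0) {
  if (!inherits(aln, "repeat_alignment")) aln <- repeat_alignment(aln)
  mat <- do.call(rbind, strsplit(aln$sequences, ""))
  L <- ncol(mat)
  counts <- vapply(seq_len(L), function(j)
    table(factor(mat[, j], levels = AA20)), integer(20))
  counts <- matrix(counts, nrow = 20, dimnames = list(AA20, NULL)) + pseudocount
  totals <- colSums(counts)
  freq <- sweep(counts, 2, pmax(totals, 1), "/")
  freq[, totals == 0] <- NA_real_
  structure(list(freq = freq,
                 gap_frac = colMeans(mat == "-"),
                 n_seq = length(aln$sequences), n_columns = L,
                 label = aln$label),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM: %d columns from %d sequences%s\n", x$n_columns, x$n_seq,
              if (is.null(x$label)) "" else paste0(" (", x$label, ")")))
  invisible(x)
}

#' Per-column information content in bits
#'
#' `IC = log2(20) - H` where `H` is the Shannon entropy of the column's
#' 20-letter distribution; ranges from 0 (uniform) to `log2(20) ~ 4.32`
#' bits (invariant column). The optional small-sample correction subtracts
#' `(20 - 1) / (2 ln(2) n)` (clamped at 0), the standard logo bias
#' adjustment; it is off by default.
#'
#' @param pfm a [build_pfm()] result.
#' @param small_sample apply the small-sample correction (default FALSE).
#' @return numeric vector of per-column bits (`NA` for all-gap columns).
#' @export
column_information <- function(pfm, small_sample = FALSE) {
  stopifnot(inherits(pfm, "pfm"))
  H <- apply(pfm$freq, 2, function(p) {
    if (anyNA(p)) return(NA_real_)
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- log2(20) - H
  if (small_sample)
    ic <- pmax(0, ic - (20 - 1) / (2 * log(2) * pfm$n_seq))
  ic
}

#' Consensus motif with conservation classes
#'
#' Collapses a PFM into the compact motif notation used for repeat
#' consensus strings. Per column, in priority order:
#' \describe{
#'   \item{complete}{top residue frequency >= `t_complete` — capital letter}
#'   \item{high}{top frequency >= `t_high` — lowercase letter}
#'   \item{hydrophobic}{summed frequency over the hydrophobic set >=
#'     `t_hydro` with no single residue >= `t_high` — the symbol `Ψ`}
#'   \item{pair}{two residues each >= `t_pair` and within a factor 2 of one
#'     another — `(x/y)` in lowercase}
#'   \item{none}{otherwise — `*`}
#' }
#'
#' @param pfm a [build_pfm()] result.
#' @param t_complete,t_high,t_hydro,t_pair class thresholds (defaults
#'   0.97, 0.60, 0.60, 0.30).
#' @param hydrophobic residue set treated as hydrophobic; default
#'   `A V L I M F W C`.
#' @return an object of class `consensus_motif`: list with `motif` (single
#'   string), `classes` (per-column factor in
#'   complete/high/hydrophobic/pair/none) and `symbols` (per-column
#'   strings).
#' @export
consensus_motif <- function(pfm, t_complete = 0.97, t_high = 0.60,
                            t_hydro = 0.60, t_pair = 0.30,
                            hydrophobic = HYDROPHOBIC_DEFAULT) {
  stopifnot(inherits(pfm, "pfm"))
  classify <- function(p) {
    if (anyNA(p)) return(c("none", "*"))
    o <- order(-p, names(p))  # deterministic: frequency, then alphabet
    r1 <- names(p)[o[1]]; f1 <- p[o[1]]
    r2 <- names(p)[o[2]]; f2 <- p[o[2]]
    if (f1 >= t_complete) return(c("complete", r1))
    if (f1 >= t_high) return(c("high", tolower(r1)))
    if (sum(p[hydrophobic]) >= t_hydro) return(c("hydrophobic", "\u03a8"))
    if (f1 >= t_pair && f2 >= t_pair && f1 <= 2 * f2)
      return(c("pair", sprintf("(%s/%s)", tolower(r1), tolower(r2))))
    c("none", "*")
  }
  res <- apply(pfm$freq, 2, classify)
  structure(list(motif = paste(res[2, ], collapse = ""),
                 classes = factor(res[1, ],
                                  levels = c("complete", "high", "hydrophobic",
                                             "pair", "none")),
                 symbols = res[2, ]),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat("consensus motif:", x$motif, "\n")
  invisible(x)
}

#' Write a per-column logo table
#'
#' TSV with one row per column: residue frequencies, gap fraction,
#' information content (bits) and consensus class/symbol.
#'
#' @param pfm a [build_pfm()] result.
#' @param path output TSV path.
#' @param motif optional [consensus_motif()]; computed with defaults when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_logo_table <- function(pfm, path, motif = NULL) {
  if (is.null(motif)) motif <- consensus_motif(pfm)
  d <- data.frame(column = seq_len(pfm$n_columns),
                  t(pfm$freq),
                  gap_frac = pfm$gap_frac,
                  bits = column_information(pfm),
                  class = as.character(motif$classes),
                  symbol = motif$symbols,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a simple sequence logo
#'
#' Thin base-graphics rendering: per column the residues are stacked in
#' order of frequency with letter heights proportional to their share of
#' the column information content. Intended for quick inspection, not
#' publication typography.
#'
#' @param x a [build_pfm()] result.
#' @param max_letters maximum letters drawn per column.
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.pfm <- function(x, max_letters = 4, ...) {
  ic <- column_information(x)
  L <- x$n_columns
  graphics::plot(NULL, xlim = c(0.5, L + 0.5), ylim = c(0, log2(20)),
                 xlab = "alignment column", ylab = "bits", bty = "n")
  for (j in seq_len(L)) {
    if (is.na(ic[j])) next
    p <- sort(x$freq[, j], decreasing = TRUE)
    p <- p[p > 0][seq_len(min(max_letters, sum(p > 0)))]
    y0 <- 0
    for (k in rev(seq_along(p))) {
      h <- ic[j] * p[k]
      graphics::text(j, y0 + h / 2, names(p)[k],
                     cex = max(0.2, min(2, 3 * h)), xpd = NA)
      y0 <- y0 + h
    }
  }
  invisible(x)
}
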