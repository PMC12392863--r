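# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes. Every generator is a pure function of
# (config, seed) and returns/attaches a ground-truth manifest so tests can
# compare pipeline output against planted truth instead of constants.

#' Reference repeat PFM used by the generators (synthetic)
#'
#' A 39-column position frequency matrix emulating the conservation
#' structure of FapC imperfect repeats: a weakly conserved N-terminal
#' stretch with an invariant Asn and Ala, followed by a strongly conserved
#' tail mixing invariant glycines, highly conserved residues, hydrophobic
#' positions and equal-frequency residue pairs. The matrix is synthetic —
#' built from the class recipe below, not from real repeat alignments —
#' and is the default generating distribution for [synth_repeat_set()].
#'
#' @return a `pfm` object (see [build_pfm()]) with an attached
#'   `attr(, "classes")` character vector giving each column's generating
#'   class.
#' @export
default_repeat_pfm <- function() {
  spec <- c("*", "*", "*", "n", "*", "*", "a", "*", "*", "*", "*", "*",
            "g", "a", "s", "G", "N", "psi", "G", "psi", "N", "psi", "a",
            "a", "G", "*", "g", "N", "q", "Q", "*", "N", "*", "psi",
            "a/s", "psi", "a/s", "*", "a/s/g")
  # Column recipes keep the residue repertoire narrow, as in real repeat
  # alignments where even unconserved positions tolerate only a handful of
  # residues; this keeps rebuilt frequencies statistically stable.
  col_for <- function(s) {
    p <- stats::setNames(rep(0, 20), AA20)
    if (s == "*") {
      p[c("S", "T", "N", "D")] <- 0.25
    } else if (s == "psi") {
      p[c("L", "V", "I", "A")] <- c(0.32, 0.27, 0.27, 0.14)
    } else if (grepl("/", s)) {
      res <- toupper(strsplit(s, "/")[[1]])
      p[res] <- 0.90 / length(res)
      rest <- setdiff(c("N", "Q", "D", "T", "E"), res)[1:5]
      rest <- rest[!is.na(rest)]
      p[rest] <- (1 - 0.90) / length(rest)
    } else if (s == toupper(s)) {          # complete conservation
      p[s] <- 0.99
      rest <- setdiff(AA20, s)
      p[rest] <- 0.01 / length(rest)
    } else {                                # high conservation
      r <- toupper(s)
      rest <- setdiff(c("S", "T", "N", "G", "D", "E"), r)[1:5]
      p[r] <- 0.75
      p[rest] <- 0.25 / length(rest)
    }
    p / sum(p)
  }
  freq <- vapply(spec, col_for, numeric(20))
  dimnames(freq) <- list(AA20, NULL)
  out <- structure(list(freq = freq, gap_frac = rep(0, length(spec)),
                        n_seq = NA_integer_, n_columns = length(spec),
                        label = "synthetic FapC-like repeat"),
                   class = "pfm")
  attr(out, "classes") <- spec
  out
}

#' Sample repeat sequences from a PFM
#'
#' Draws `n` sequences column-independently from the PFM; when a column
#' carries a nonzero gap fraction, a gap character is emitted with that
#' probability and a residue from the column distribution otherwise.
#'
#' @param pfm a `pfm` object.
#' @param n number of sequences; >= 1.
#' @param seed RNG seed (NULL uses the current stream).
#' @return character vector of `n` sequences of length `pfm$n_columns`.
#' @export
synth_repeat_set <- function(pfm, n, seed = NULL) {
  stopifnot(inherits(pfm, "pfm"))
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("'n' must be >= 1", call. = FALSE)
  with_seed_(seed, {
    cols <- lapply(seq_len(pfm$n_columns), function(j) {
      res <- sample(AA20, n, replace = TRUE, prob = pfm$freq[, j])
      gf <- pfm$gap_frac[j]
      if (gf > 0) res[stats::runif(n) < gf] <- "-"
      res
    })
    do.call(paste0, cols)
  })
}

#' Synthetic SAXS curve from the cylinder + polymer model
#'
#' Forward-simulates `I = model_intensity(q, p) * (1 + e)`, with
#' `e ~ Normal(0, noise_frac)` i.i.d., and reports
#' `sigma = noise_frac * I_model`. With `noise_frac = 0` the exact model
#' curve is returned with a nominal small sigma so the curve stays usable
#' in weighted fits.
#'
#' @param p a [cylinder_params()] object.
#' @param noise_frac relative noise level (e.g. 0.01 for 1%).
#' @param q_grid scattering vector, nm^-1.
#' @param seed RNG seed (NULL uses the current stream).
#' @return a [saxs_curve()] with the generating parameters attached as
#'   `attr(, "truth")`.
#' @export
synth_saxs_curve <- function(p, noise_frac, q_grid, seed = NULL) {
  stopifnot(inherits(p, "cylinder_params"))
  if (noise_frac < 0) stop("'noise_frac' must be >= 0", call. = FALSE)
  I0 <- model_intensity(q_grid, p)
  I <- if (noise_frac > 0)
    with_seed_(seed, I0 * (1 + stats::rnorm(length(q_grid), 0, noise_frac)))
  else I0
  sigma <- pmax(noise_frac, 1e-6) * abs(I0)
  out <- saxs_curve(q_grid, I, sigma)
  attr(out, "truth") <- p
  out
}

#' Synthetic helical pseudo-atom trace
#'
#' A planar motif of `atoms_per_layer` pseudo-atoms (seeded uniform points
#' in an annulus, small axial jitter) repeated `n_layers` times by
#' [build_helical_assembly()], emulating the stacked cross-beta layers of
#' a fibril. The generating symmetry and motif are attached as ground
#' truth.
#'
#' @param p a [helical_params()] object.
#' @param n_layers number of symmetry copies; >= 1.
#' @param atoms_per_layer pseudo-atoms per layer (default 10).
#' @param seed RNG seed.
#' @return an [atomic_model()] with `attr(, "truth")` containing `params`
#'   and `motif`.
#' @export
synth_helical_trace <- function(p, n_layers, atoms_per_layer = 10,
                                seed = NULL) {
  stopifnot(inherits(p, "helical_params"))
  if (n_layers < 1) stop("'n_layers' must be >= 1", call. = FALSE)
  motif <- with_seed_(seed, {
    r <- stats::runif(atoms_per_layer, 2, 12)
    th <- stats::runif(atoms_per_layer, 0, 2 * pi)
    atomic_model(element = "C", resid = seq_len(atoms_per_layer), chain = "A",
                 x = r * cos(th), y = r * sin(th),
                 z = stats::runif(atoms_per_layer, -1.2, 1.2))
  })
  out <- build_helical_assembly(motif, p, n_layers)
  attr(out, "truth") <- list(params = p, motif = motif)
  out
}

#' Synthetic AFM height profile
#'
#' `height = baseline + amplitude * sin(2 pi x / period + phase) + noise`
#' on a uniform grid, with a seeded random phase and i.i.d. Gaussian
#' noise. Sampling must satisfy `dx < period / 4`, otherwise the
#' modulation would be near the Nyquist limit and the configuration is
#' rejected.
#'
#' @param period_nm modulation period, nm; > 0.
#' @param amplitude_nm modulation amplitude, nm (default 1, the height
#'   variation scale of a twisted fibril silhouette).
#' @param noise_sd additive noise standard deviation, nm (default 0.2).
#' @param length_nm profile length, nm (default 1000).
#' @param dx_nm sampling step, nm (default 2).
#' @param baseline_nm mean fibril height, nm (default 2).
#' @param seed RNG seed.
#' @return a [height_profile()] with `attr(, "truth")` giving the
#'   generating parameters.
#' @export
synth_height_profile <- function(period_nm, amplitude_nm = 1, noise_sd = 0.2,
                                 length_nm = 1000, dx_nm = 2,
                                 baseline_nm = 2, seed = NULL) {
  stop_scalar(period_nm, "period_nm", positive = TRUE)
  if (dx_nm >= period_nm / 4)
    stop("aliasing: need dx_nm < period_nm / 4", call. = FALSE)
  x <- seq(0, length_nm, by = dx_nm)
  with_seed_(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    h <- baseline_nm + amplitude_nm * sin(2 * pi * x / period_nm + phase) +
      stats::rnorm(length(x), 0, noise_sd)
    out <- height_profile(x, h)
    attr(out, "truth") <- list(period_nm = period_nm,
                               amplitude_nm = amplitude_nm,
                               noise_sd = noise_sd, phase = phase)
    out
  })
}

random_protein <- function(n_aa) {
  paste(sample(AA20, n_aa, replace = TRUE), collapse = "")
}

# One domtblout-formatted row (22 columns + description).
domtbl_row <- function(gene_id, tlen, hmm, qlen, full_e, full_score,
                       dom_idx, dom_of, dom_e, dom_score,
                       ali_from, ali_to) {
  sprintf(paste("%s - %d %s - %d %.2g %.1f 0.1 %d %d %.2g %.2g %.1f 0.1",
                "1 %d %d %d %d %d 0.95 synthetic"),
          gene_id, tlen, hmm, qlen, full_e, full_score, dom_idx, dom_of,
          dom_e, dom_e, dom_score, qlen, ali_from, ali_to,
          max(1, ali_from - 2), ali_to + 2)
}

#' Synthesize a Fap genome: gene table, domtblout and protein FASTA
#'
#' Plants `n_operons` fapABCDEF-ordered operons (one per contig) with
#' configurable intergenic gaps and per-gene repeat counts, plus optional
#' decoy genes whose hits fail the E-value cutoff. Emits the three files
#' the mining pipeline consumes — gene coordinate TSV, HMMER3-dialect
#' domtblout and protein FASTA — and returns a ground-truth manifest.
#'
#' Config entries (all optional):
#' \describe{
#'   \item{n_operons}{number of planted operons (default 10)}
#'   \item{gap_bp}{intergenic gap: scalar, per-operon vector, or list of
#'     per-operon length-5 vectors (gaps between the 6 genes); default 200}
#'   \item{n_repeats_fapB, n_repeats_fapC}{repeat counts, scalar or
#'     per-operon vector (default 3)}
#'   \item{genes}{HMM identities planted per operon, in order (default
#'     FapA, FapBC_repeat, FapBC_repeat, FapD, FapE, FapF)}
#'   \item{n_decoys}{genes on separate contigs with hits above the cutoff
#'     (default 0)}
#'   \item{hit_evalue, decoy_evalue}{E-values for planted/decoy hits
#'     (defaults 1e-30 and 1e-3)}
#'   \item{genome_id}{default "synth_genome_1"}
#' }
#'
#' @param cfg configuration list, see Details.
#' @param out_dir output directory (created); default a fresh tempdir.
#' @param seed RNG seed.
#' @return list with `genes_path`, `domtblout_path`, `fasta_path` and
#'   `manifest` (per-gene data frame with planted roles and repeat counts,
#'   plus `n_operons`).
#' @export
synth_fap_genome <- function(cfg = list(), out_dir = tempfile("fap_synth_"),
                             seed = NULL) {
  defaults <- list(n_operons = 10, gap_bp = 200,
                   n_repeats_fapB = 3, n_repeats_fapC = 3,
                   genes = c("FapA", "FapBC_repeat", "FapBC_repeat",
                             "FapD", "FapE", "FapF"),
                   n_decoys = 0, hit_evalue = 1e-30, decoy_evalue = 1e-3,
                   genome_id = "synth_genome_1")
  if (length(bad <- setdiff(names(cfg), names(defaults))))
    stop("unknown config entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, cfg)
  nop <- cfg$n_operons
  if (nop < 0 || cfg$n_decoys < 0)
    stop("contradictory config: negative counts", call. = FALSE)
  n_genes <- length(cfg$genes)
  expand_per_operon <- function(x, nm) {
    if (length(x) == 1) rep(x, nop)
    else if (length(x) == nop) x
    else stop(sprintf("contradictory config: '%s' must have length 1 or n_operons", nm),
              call. = FALSE)
  }
  reps_B <- expand_per_operon(cfg$n_repeats_fapB, "n_repeats_fapB")
  reps_C <- expand_per_operon(cfg$n_repeats_fapC, "n_repeats_fapC")
  gaps <- cfg$gap_bp
  gap_list <- if (is.list(gaps)) {
    if (length(gaps) != nop)
      stop("contradictory config: gap_bp list must have n_operons entries",
           call. = FALSE)
    lapply(gaps, function(g) {
      if (length(g) == 1) rep(g, n_genes - 1)
      else if (length(g) == n_genes - 1) g
      else stop("contradictory config: per-operon gaps must have length genes - 1",
                call. = FALSE)
    })
  } else {
    g <- expand_per_operon(gaps, "gap_bp")
    lapply(g, function(x) rep(x, n_genes - 1))
  }

  pfm <- default_repeat_pfm()
  rep_len <- pfm$n_columns
  rep_spacing <- rep_len + 16L  # linker between planted repeats

  with_seed_(seed, {
    rows <- list(); dom_lines <- character(0); prot <- character(0)
    manifest <- list()
    bc_seen <- 0L
    for (i in seq_len(nop)) {
      contig <- sprintf("ctg_%03d", i)
      pos <- 1000L
      for (k in seq_len(n_genes)) {
        hmm <- cfg$genes[k]
        gid <- sprintf("op%03d_g%d_%s", i, k, sub("_repeat", "", hmm))
        role <- c("fapA", "fapB", "fapC", "fapD", "fapE", "fapF")[
          match(hmm, c("FapA", "FapBC_repeat", "FapBC_repeat",
                       "FapD", "FapE", "FapF"))]
        n_rep <- NA_integer_
        if (hmm == "FapBC_repeat") {
          is_first_bc <- !any(vapply(manifest, function(m)
            m$operon == i && m$hmm == "FapBC_repeat", logical(1)))
          role <- if (is_first_bc) "fapB" else "fapC"
          n_rep <- if (is_first_bc) reps_B[i] else reps_C[i]
        }
        aa_len <- switch(hmm, FapA = 150L, FapD = 230L, FapE = 120L,
                         FapF = 430L,
                         FapBC_repeat = 45L + (n_rep - 1L) * rep_spacing +
                           rep_len + 30L)
        bp_len <- aa_len * 3L + 3L
        start <- pos; end <- pos + bp_len - 1L
        pos <- end + gap_list[[i]][min(k, n_genes - 1)] + 1L
        seq_aa <- random_protein(aa_len)
        if (hmm == "FapBC_repeat") {
          starts <- 45L + (seq_len(n_rep) - 1L) * rep_spacing
          reps <- synth_repeat_set(pfm, n_rep)
          for (r in seq_len(n_rep)) {
            substr(seq_aa, starts[r], starts[r] + rep_len - 1L) <- reps[r]
            dom_lines <- c(dom_lines, domtbl_row(
              gid, aa_len, hmm, rep_len, cfg$hit_evalue,
              60 * n_rep, r, n_rep, cfg$hit_evalue,
              55 + stats::runif(1, -5, 5),
              starts[r], starts[r] + rep_len - 1L))
          }
        } else {
          dom_lines <- c(dom_lines, domtbl_row(
            gid, aa_len, hmm, aa_len - 20L, cfg$hit_evalue, 180, 1L, 1L,
            cfg$hit_evalue, 175, 10L, aa_len - 10L))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, genome_id = cfg$genome_id, contig_id = contig,
          start = start, end = end, strand = "+", aa_length = aa_len,
          stringsAsFactors = FALSE)
        prot[gid] <- seq_aa
        manifest[[length(manifest) + 1L]] <- list(
          operon = i, gene_id = gid, hmm = hmm, role = role,
          contig = contig, n_repeats = n_rep)
      }
    }
    for (d in seq_len(cfg$n_decoys)) {
      gid <- sprintf("decoy_%03d", d)
      contig <- sprintf("decoy_ctg_%03d", d)
      aa_len <- 200L
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, genome_id = cfg$genome_id, contig_id = contig,
        start = 1000L, end = 1000L + aa_len * 3L + 2L, strand = "+",
        aa_length = aa_len, stringsAsFactors = FALSE)
      dom_lines <- c(dom_lines, domtbl_row(
        gid, aa_len, sample(FAP_HMMS, 1), 100L, cfg$decoy_evalue, 12, 1L, 1L,
        cfg$decoy_evalue, 11, 20L, 120L))
      prot[gid] <- random_protein(aa_len)
      manifest[[length(manifest) + 1L]] <- list(
        operon = NA_integer_, gene_id = gid, hmm = "decoy", role = "decoy",
        contig = contig, n_repeats = NA_integer_)
    }

    genes <- do.call(rbind, rows)
    man <- do.call(rbind, lapply(manifest, function(m)
      data.frame(m, stringsAsFactors = FALSE)))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    genes_path <- file.path(out_dir, "genes.tsv")
    dom_path <- file.path(out_dir, "hits.domtblout")
    fasta_path <- file.path(out_dir, "proteins.fasta")
    utils::write.table(genes, genes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(c(
      "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
      "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
      "#------------------- ----------", dom_lines), dom_path)
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(prot), fasta_path)
    list(genes_path = genes_path, domtblout_path = dom_path,
         fasta_path = fasta_path,
         manifest = list(genes = man, n_operons = nop,
                         genome_id = cfg$genome_id))
  })
}
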