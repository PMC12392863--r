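FAP_HMMS <- c("FapA", "FapBC_repeat", "FapD", "FapE", "FapF")

#' Parse a HMMER3 per-domain hit table (domtblout)
#'
#' Reads the whitespace-separated per-domain tabular output of `hmmsearch`
#' (`--domtblout`): `#` comment lines are skipped, the 22 fixed columns are
#' parsed and the free-text description tail ignored. One row is returned
#' per reported domain. Hits whose full-sequence E-value exceeds the cutoff
#' (default 1e-5) are dropped; optionally the per-domain independent
#' E-value is filtered as well. Input row order is preserved.
#'
#' @param path path to a domtblout file.
#' @param evalue full-sequence E-value cutoff; rows with larger E-values
#'   are dropped (default `1e-5`).
#' @param per_domain also require the domain independent E-value (column
#'   13) to pass the cutoff (default `FALSE`).
#' @return data frame of domain hits with columns `gene_id`, `hmm_name`,
#'   `full_seq_evalue`, `full_seq_bitscore`, `domain_index`,
#'   `dom_i_evalue`, `dom_bitscore`, `ali_from_aa`, `ali_to_aa`.
#' @export
parse_domtblout <- function(path, evalue = 1e-5, per_domain = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(data_idx))
    return(empty_domain_hits())
  parse_row <- function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22)
      stop(sprintf("malformed domtblout row at line %d: %d columns before description (expected 22)",
                   i, length(f)), call. = FALSE)
    num <- suppressWarnings(as.numeric(f[c(7, 8, 10, 13, 14, 18, 19)]))
    if (anyNA(num))
      stop(sprintf("malformed domtblout row at line %d: non-numeric field", i),
           call. = FALSE)
    if (num[6] > num[7])
      stop(sprintf("malformed domtblout row at line %d: ali_from > ali_to", i),
           call. = FALSE)
    data.frame(gene_id = f[1], hmm_name = f[4],
               full_seq_evalue = num[1], full_seq_bitscore = num[2],
               domain_index = as.integer(num[3]),
               dom_i_evalue = num[4], dom_bitscore = num[5],
               ali_from_aa = as.integer(num[6]), ali_to_aa = as.integer(num[7]),
               stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, lapply(data_idx, parse_row))
  keep <- hits$full_seq_evalue <= evalue
  if (per_domain) keep <- keep & hits$dom_i_evalue <= evalue
  hits[keep, , drop = FALSE]
}

empty_domain_hits <- function() {
  data.frame(gene_id = character(), hmm_name = character(),
             full_seq_evalue = numeric(), full_seq_bitscore = numeric(),
             domain_index = integer(), dom_i_evalue = numeric(),
             dom_bitscore = numeric(), ali_from_aa = integer(),
             ali_to_aa = integer(), stringsAsFactors = FALSE)
}

#' Read a gene coordinate table
#'
#' Tab-separated with header columns `gene_id`, `genome_id`, `contig_id`,
#' `start`, `end`, `strand`, `aa_length`. Coordinates are 1-based and
#' inclusive; `end >= start` and `aa_length >= 1` are enforced, and
#' `gene_id` must be unique within each genome.
#'
#' @param path file path.
#' @return data frame of gene records.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "genome_id", "contig_id", "start", "end", "strand",
            "aa_length")
  if (length(miss <- setdiff(need, names(g))))
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  validate_gene_table(g)
}

validate_gene_table <- function(g) {
  if (any(g$end < g$start)) stop("gene with end < start", call. = FALSE)
  if (any(g$aa_length < 1)) stop("gene with aa_length < 1", call. = FALSE)
  if (anyDuplicated(paste(g$genome_id, g$gene_id)))
    stop("gene_id not unique within genome", call. = FALSE)
  g
}

# Best single HMM annotation per gene: highest full-sequence bitscore.
best_annotation <- function(hits) {
  if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
  o <- order(hits$gene_id, -hits$full_seq_bitscore)
  h <- hits[o, ]
  h <- h[!duplicated(h$gene_id), ]
  stats::setNames(h$hmm_name, h$gene_id)
}

#' Cluster HMM-hit genes along contigs
#'
#' Single-linkage chaining of genes on each contig: two genes adjacent in
#' genomic order join the same cluster iff their intergenic distance
#' (downstream `start` minus upstream `end`, minus 1) is strictly less
#' than `max_gap_bp`. The result is a partition of the input genes,
#' invariant under permutation of input order. Each gene is annotated with
#' its best-scoring HMM.
#'
#' @param genes gene table (see [read_gene_table()]) restricted to genes
#'   with at least one retained hit, or a full table from which hit genes
#'   are selected using `hits`.
#' @param hits domain-hit table from [parse_domtblout()]; used to restrict
#'   `genes` and derive per-gene HMM annotations.
#' @param max_gap_bp clustering threshold in bp; default 5000 with strict
#'   `<` comparison.
#' @return list of `gene_cluster` objects, each with `genome_id`,
#'   `contig_id`, `genes` (ordered by `start`) and `hmm` (named character
#'   vector gene_id -> hmm_name).
#' @export
cluster_genes <- function(genes, hits, max_gap_bp = 5000) {
  if (!"genome_id" %in% names(genes) || anyNA(genes$genome_id))
    stop("genes must carry a genome_id", call. = FALSE)
  validate_gene_table(genes)
  ann <- best_annotation(hits)
  genes <- genes[genes$gene_id %in% names(ann), , drop = FALSE]
  clusters <- list()
  for (key in unique(paste(genes$genome_id, genes$contig_id, sep = "\r"))) {
    sub <- genes[paste(genes$genome_id, genes$contig_id, sep = "\r") == key, ,
                 drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    gaps <- if (nrow(sub) > 1)
      sub$start[-1] - sub$end[-nrow(sub)] - 1L else integer(0)
    grp <- cumsum(c(1L, as.integer(gaps >= max_gap_bp)))
    for (gi in unique(grp)) {
      block <- sub[grp == gi, , drop = FALSE]
      clusters[[length(clusters) + 1L]] <- structure(
        list(genome_id = block$genome_id[1], contig_id = block$contig_id[1],
             genes = block, hmm = ann[block$gene_id]),
        class = "gene_cluster")
    }
  }
  clusters
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("gene cluster on %s/%s: %d genes [%s]\n", x$genome_id,
              x$contig_id, nrow(x$genes), paste(x$hmm, collapse = ", ")))
  invisible(x)
}

#' Keep clusters with Fap-operon structure
#'
#' A cluster is retained when it contains at least one gene with
#' FapBC_repeat homology and at least 3 additional HMM-hit genes (cluster
#' size >= 4). Genes are counted as genes, not as distinct HMM identities.
#'
#' @param clusters list of clusters from [cluster_genes()].
#' @return the retained subset of `clusters`.
#' @export
filter_fap_clusters <- function(clusters) {
  Filter(function(cl) {
    n_bc <- sum(cl$hmm == "FapBC_repeat")
    n_bc >= 1 && (nrow(cl$genes) - 1L) >= 3L
  }, clusters)
}

#' Designate fapB and fapC by synteny
#'
#' In the fapABCDEF operon the nucleator gene fapB precedes the major
#' subunit gene fapC; under a combined FapBC_repeat homology model the two
#' cannot be told apart by score, so the first FapBC_repeat gene in genomic
#' order is designated fapB and the second fapC. Clusters with exactly one
#' FapBC_repeat gene leave both designations absent (such clusters are
#' excluded from the repeat census); clusters with more than two are
#' flagged for review (first two assigned, a warning is emitted).
#'
#' @param cluster a `gene_cluster` that passed [filter_fap_clusters()].
#' @return an object of class `fap_operon` with fields `cluster`,
#'   `fapB_gene_id`, `fapC_gene_id` (either may be `NA`), `role_map` and
#'   `review` flag.
#' @export
assign_fapB_fapC <- function(cluster) {
  stopifnot(inherits(cluster, "gene_cluster"))
  bc <- cluster$genes$gene_id[cluster$hmm[cluster$genes$gene_id] == "FapBC_repeat"]
  fapB <- fapC <- NA_character_
  review <- FALSE
  if (length(bc) >= 2) {
    fapB <- bc[1]; fapC <- bc[2]
    if (length(bc) > 2) {
      review <- TRUE
      warning(sprintf("cluster on %s/%s has %d FapBC_repeat genes; first two assigned, flagged for review",
                      cluster$genome_id, cluster$contig_id, length(bc)),
              call. = FALSE)
    }
  }
  role_map <- vapply(cluster$genes$gene_id, function(g) {
    if (identical(g, fapB)) return("fapB")
    if (identical(g, fapC)) return("fapC")
    switch(cluster$hmm[[g]],
           FapA = "fapA", FapD = "fapD", FapE = "fapE", FapF = "fapF",
           FapBC_repeat = "fapBC_unassigned", "other")
  }, character(1))
  structure(list(cluster = cluster, fapB_gene_id = fapB, fapC_gene_id = fapC,
                 role_map = role_map, review = review),
            class = "fap_operon")
}

#' @export
print.fap_operon <- function(x, ...) {
  cat(sprintf("fap operon on %s/%s: fapB = %s, fapC = %s%s\n",
              x$cluster$genome_id, x$cluster$contig_id,
              x$fapB_gene_id, x$fapC_gene_id,
              if (x$review) " [REVIEW: >2 FapBC_repeat genes]" else ""))
  invisible(x)
}

#' Census imperfect repeats on a gene
#'
#' FapBC_repeat domain hits on one gene are resolved into an ordered set of
#' imperfect repeats (IR1, IR2, ...). Domains are first deduplicated:
#' whenever two domains overlap by more than 50% of the shorter alignment,
#' only the higher-scoring one (per-domain bitscore) is kept. Survivors are
#' numbered in ascending alignment-start order.
#'
#' @param gene_id the gene to census.
#' @param hits domain-hit table from [parse_domtblout()]; only
#'   `FapBC_repeat` rows for `gene_id` are used.
#' @param protein optional amino-acid sequence of the gene product, used to
#'   attach repeat sequences.
#' @return data frame of repeat instances with columns `gene_id`,
#'   `ir_index`, `start_aa`, `end_aa`, `sequence` (NA when no `protein`).
#' @export
count_repeats <- function(gene_id, hits, protein = NULL) {
  h <- hits[hits$gene_id == gene_id & hits$hmm_name == "FapBC_repeat", ,
            drop = FALSE]
  if (!nrow(h))
    return(data.frame(gene_id = character(), ir_index = integer(),
                      start_aa = integer(), end_aa = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  # greedy overlap resolution, best domain score first
  h <- h[order(-h$dom_bitscore, h$ali_from_aa), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(h))) {
    ov <- FALSE
    for (k in kept) {
      inter <- min(h$ali_to_aa[i], h$ali_to_aa[k]) -
        max(h$ali_from_aa[i], h$ali_from_aa[k]) + 1L
      shorter <- min(h$ali_to_aa[i] - h$ali_from_aa[i],
                     h$ali_to_aa[k] - h$ali_from_aa[k]) + 1L
      if (inter > 0.5 * shorter) { ov <- TRUE; break }
    }
    if (!ov) kept <- c(kept, i)
  }
  h <- h[kept, , drop = FALSE]
  h <- h[order(h$ali_from_aa), , drop = FALSE]
  seqs <- rep(NA_character_, nrow(h))
  if (!is.null(protein)) {
    protein <- as.character(protein)
    seqs <- substring(protein, h$ali_from_aa, h$ali_to_aa)
  }
  data.frame(gene_id = gene_id, ir_index = seq_len(nrow(h)),
             start_aa = h$ali_from_aa, end_aa = h$ali_to_aa,
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Histograms summarising a set of fap operons
#'
#' Tabulates the mined operons: genes per cluster, FapBC_repeat genes per
#' cluster, repeats per fapB and per fapC gene, gene length (aa)
#' distributions restricted to genes with exactly 3 repeats, and the
#' length distribution of the individual repeats. Histogram totals equal
#' the corresponding input cardinalities.
#'
#' @param operons list of [assign_fapB_fapC()] results.
#' @param repeats named list mapping gene_id to a [count_repeats()] data
#'   frame.
#' @return an object of class `fap_census`: a list of `table`s /
#'   numeric vectors.
#' @export
operon_census <- function(operons, repeats = list()) {
  n_genes <- vapply(operons, function(o) nrow(o$cluster$genes), integer(1))
  n_bc <- vapply(operons, function(o)
    sum(o$cluster$hmm == "FapBC_repeat"), integer(1))
  rep_count <- function(gid) {
    if (is.na(gid) || is.null(repeats[[gid]])) NA_integer_
    else nrow(repeats[[gid]])
  }
  aa_len <- function(o, gid) {
    g <- o$cluster$genes
    g$aa_length[match(gid, g$gene_id)]
  }
  nB <- nC <- integer(0)
  lenB3 <- lenC3 <- numeric(0)
  rep_lengths <- integer(0)
  for (o in operons) {
    if (!is.na(o$fapB_gene_id) && !is.na(o$fapC_gene_id)) {
      rb <- rep_count(o$fapB_gene_id); rc <- rep_count(o$fapC_gene_id)
      if (!is.na(rb)) {
        nB <- c(nB, rb)
        if (rb == 3L) lenB3 <- c(lenB3, aa_len(o, o$fapB_gene_id))
      }
      if (!is.na(rc)) {
        nC <- c(nC, rc)
        if (rc == 3L) lenC3 <- c(lenC3, aa_len(o, o$fapC_gene_id))
      }
    }
  }
  for (r in repeats)
    if (nrow(r)) rep_lengths <- c(rep_lengths, r$end_aa - r$start_aa + 1L)
  structure(list(
    genes_per_cluster = table(n_genes),
    fapBC_per_cluster = table(n_bc),
    repeats_per_fapB = table(nB),
    repeats_per_fapC = table(nC),
    gene_length_fapB_3rep = lenB3,
    gene_length_fapC_3rep = lenC3,
    repeat_lengths = table(rep_lengths),
    n_operons = length(operons)
  ), class = "fap_census")
}

#' @export
print.fap_census <- function(x, ...) {
  cat(sprintf("fap operon census over %d operons\n", x$n_operons))
  cat("genes per cluster:\n"); print(x$genes_per_cluster)
  cat("repeats per fapC gene:\n"); print(x$repeats_per_fapC)
  invisible(x)
}

#' Run the full operon-mining pipeline on files
#'
#' Convenience wrapper: parse the domtblout, read the gene table, cluster,
#' filter, designate fapB/fapC, census repeats on every designated fapB and
#' fapC gene, and tabulate.
#'
#' @param domtblout_path HMMER3 domtblout file.
#' @param genes_path gene coordinate TSV.
#' @param evalue full-sequence E-value cutoff.
#' @param max_gap_bp clustering threshold, bp.
#' @return list with `hits`, `clusters`, `operons`, `repeats`, `census`.
#' @export
mine_fap_operons <- function(domtblout_path, genes_path,
                             evalue = 1e-5, max_gap_bp = 5000) {
  hits <- parse_domtblout(domtblout_path, evalue = evalue)
  genes <- read_gene_table(genes_path)
  clusters <- cluster_genes(genes, hits, max_gap_bp = max_gap_bp)
  kept <- filter_fap_clusters(clusters)
  operons <- lapply(kept, assign_fapB_fapC)
  repeats <- list()
  for (o in operons) {
    for (gid in c(o$fapB_gene_id, o$fapC_gene_id)) {
      if (!is.na(gid)) repeats[[gid]] <- count_repeats(gid, hits)
    }
  }
  list(hits = hits, clusters = clusters, operons = operons,
       repeats = repeats, census = operon_census(operons, repeats))
}

#' Write operon-mining outputs as TSV
#'
#' Writes an operon table (`operons.tsv`), a repeat-instance table
#' (`repeats.tsv`) and the census histograms (`census_*.tsv`) into a
#' directory.
#'
#' @param mined result of [mine_fap_operons()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mining_tables <- function(mined, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  op <- do.call(rbind, lapply(mined$operons, function(o)
    data.frame(genome_id = o$cluster$genome_id, contig_id = o$cluster$contig_id,
               n_genes = nrow(o$cluster$genes),
               fapB = o$fapB_gene_id, fapC = o$fapC_gene_id,
               review = o$review, stringsAsFactors = FALSE)))
  utils::write.table(op, file.path(dir, "operons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reps <- do.call(rbind, mined$repeats)
  if (!is.null(reps))
    utils::write.table(reps, file.path(dir, "repeats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (nm in c("genes_per_cluster", "fapBC_per_cluster",
               "repeats_per_fapB", "repeats_per_fapC", "repeat_lengths")) {
    tb <- as.data.frame(mined$census[[nm]])
    utils::write.table(tb, file.path(dir, paste0("census_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
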