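# hand-built domtblout rows matching the HMMER3 per-domain dialect
dom_line <- function(gene, hmm, full_e, dom_score, from, to,
                     tlen = 300, qlen = 39, idx = 1, of = 1) {
  sprintf("%s - %d %s - %d %g 120.0 0.1 %d %d %g %g %.1f 0.1 1 %d %d %d %d %d 0.95 test fixture",
          gene, tlen, hmm, qlen, full_e, idx, of, full_e, full_e,
          dom_score, qlen, from, to, from, to)
}

write_dom <- function(lines) {
  path <- withr::local_tempfile(fileext = ".domtblout",
                                .local_envir = parent.frame())
  writeLines(c("# hmmsearch :: per-domain hits", lines), path)
  path
}

gene_row <- function(gene_id, start, end, contig = "c1",
                     genome = "g1", aa = 300) {
  data.frame(gene_id = gene_id, genome_id = genome, contig_id = contig,
             start = start, end = end, strand = "+", aa_length = aa,
             stringsAsFactors = FALSE)
}

test_that("domtblout parsing keeps rows passing the e-value cutoff", {
  path <- write_dom(c(
    dom_line("gA", "FapA", 1e-8, 50, 10, 120),
    dom_line("gB", "FapBC_repeat", 1e-6, 45, 45, 83),
    dom_line("gC", "FapD", 1e-3, 20, 5, 200)))
  hits <- parse_domtblout(path)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$gene_id, c("gA", "gB"))
  expect_equal(hits$ali_from_aa, c(10L, 45L))

  # comment-only file -> empty result
  empty <- write_dom(character(0))
  expect_equal(nrow(parse_domtblout(empty)), 0)

  # ali_from > ali_to is a parse error naming the line
  bad <- write_dom(dom_line("gX", "FapA", 1e-9, 50, 120, 10))
  expect_error(parse_domtblout(bad), "line 2")

  # truncated row is a parse error
  trunc <- withr::local_tempfile(fileext = ".domtblout")
  writeLines("gY - 300 FapA - 100 1e-9 50", trunc)
  expect_error(parse_domtblout(trunc), "malformed")

  expect_error(parse_domtblout(tempfile()), "not found")
})

test_that("gene clustering joins genes strictly below the bp threshold", {
  genes <- rbind(gene_row("g1", 1000, 2000), gene_row("g2", 7000, 8000))
  hits <- parse_domtblout(write_dom(c(
    dom_line("g1", "FapA", 1e-9, 50, 10, 100),
    dom_line("g2", "FapD", 1e-9, 50, 10, 100))))
  # intergenic distance 4999 (< 5000): one cluster
  cl <- cluster_genes(genes, hits)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$genes), 2)
  # distance exactly 5000: split
  genes2 <- rbind(gene_row("g1", 1000, 2000), gene_row("g2", 7001, 8000))
  expect_length(cluster_genes(genes2, hits), 2)
})

test_that("clustering is order-invariant and matches the brute-force oracle", {
  withr::with_seed(42, {
    for (trial in 1:8) {
      n <- sample(10:50, 1)
      # random non-overlapping genes over 2 contigs
      contigs <- sample(c("cA", "cB"), n, replace = TRUE)
      genes <- do.call(rbind, lapply(seq_len(n), function(i) {
        gene_row(paste0("g", i), 0, 0, contig = contigs[i])
      }))
      for (ctg in unique(contigs)) {
        idx <- which(genes$contig_id == ctg)
        pos <- 1000
        for (i in idx) {
          len <- sample(300:3000, 1)
          genes$start[i] <- pos
          genes$end[i] <- pos + len
          pos <- pos + len + sample(c(100:2000, 4000:7000), 1)
        }
      }
      hits <- data.frame(gene_id = genes$gene_id, hmm_name = "FapD",
                         full_seq_evalue = 1e-9, full_seq_bitscore = 50,
                         domain_index = 1L, dom_i_evalue = 1e-9,
                         dom_bitscore = 50, ali_from_aa = 1L,
                         ali_to_aa = 100L, stringsAsFactors = FALSE)
      cl <- cluster_genes(genes, hits)
      got <- lapply(cl, function(x) sort(x$genes$gene_id))
      want <- lapply(brute_force_clusters(genes, 5000), sort)
      expect_setequal(lapply(got, paste, collapse = ","),
                      lapply(want, paste, collapse = ","))
      # partition: every gene in exactly one cluster
      all_ids <- unlist(lapply(cl, function(x) x$genes$gene_id))
      expect_setequal(all_ids, genes$gene_id)
      expect_equal(length(all_ids), n)
      # order invariance
      perm <- genes[sample(n), ]
      cl_perm <- cluster_genes(perm, hits)
      got_perm <- sort(sapply(cl_perm, function(x)
        paste(sort(x$genes$gene_id), collapse = ",")))
      expect_equal(sort(sapply(cl, function(x)
        paste(sort(x$genes$gene_id), collapse = ","))), got_perm)
      # translation invariance of a whole contig
      shifted <- genes
      shifted$start[shifted$contig_id == "cA"] <-
        shifted$start[shifted$contig_id == "cA"] + 123456
      shifted$end[shifted$contig_id == "cA"] <-
        shifted$end[shifted$contig_id == "cA"] + 123456
      got_shift <- sort(sapply(cluster_genes(shifted, hits), function(x)
        paste(sort(x$genes$gene_id), collapse = ",")))
      expect_equal(got_shift, got_perm)
    }
  })
  expect_error(cluster_genes(within(gene_row("g1", 1, 10), rm(genome_id)),
                             NULL), "genome_id")
})

fixture_cluster <- function(hmms, starts = NULL) {
  n <- length(hmms)
  if (is.null(starts)) starts <- seq(1000, by = 3000, length.out = n)
  genes <- do.call(rbind, lapply(seq_len(n), function(i)
    gene_row(paste0("g", i), starts[i], starts[i] + 2000)))
  structure(list(genome_id = "g1", contig_id = "c1", genes = genes,
                 hmm = stats::setNames(hmms, genes$gene_id)),
            class = "gene_cluster")
}

test_that("fap-cluster filter requires FapBC homology plus 3 other genes", {
  full <- fixture_cluster(c("FapA", "FapBC_repeat", "FapBC_repeat",
                            "FapD", "FapE", "FapF"))
  small <- fixture_cluster(c("FapBC_repeat", "FapD", "FapE"))
  no_bc <- fixture_cluster(c("FapA", "FapD", "FapE", "FapF"))
  kept <- filter_fap_clusters(list(full, small, no_bc))
  expect_length(kept, 1)
  expect_identical(kept[[1]], full)
  expect_length(filter_fap_clusters(list()), 0)
})

test_that("fapB/fapC designation follows genomic order of FapBC genes", {
  cl <- fixture_cluster(c("FapA", "FapBC_repeat", "FapD", "FapBC_repeat",
                          "FapE", "FapF"),
                        starts = c(1000, 3000, 5000, 9000, 12000, 15000))
  op <- assign_fapB_fapC(cl)
  expect_equal(op$fapB_gene_id, "g2")  # start 3000
  expect_equal(op$fapC_gene_id, "g4")  # start 9000
  expect_false(op$review)
  expect_equal(unname(op$role_map[c("g2", "g4")]), c("fapB", "fapC"))

  one_bc <- fixture_cluster(c("FapA", "FapBC_repeat", "FapD", "FapE"))
  op1 <- assign_fapB_fapC(one_bc)
  expect_true(is.na(op1$fapB_gene_id))
  expect_true(is.na(op1$fapC_gene_id))

  three_bc <- fixture_cluster(c("FapBC_repeat", "FapBC_repeat",
                                "FapBC_repeat", "FapD", "FapE"))
  expect_warning(op3 <- assign_fapB_fapC(three_bc), "review")
  expect_true(op3$review)
  expect_equal(op3$fapB_gene_id, "g1")
  expect_equal(op3$fapC_gene_id, "g2")
})

test_that("repeat census orders domains and resolves >50% overlaps by score", {
  path <- write_dom(c(
    dom_line("fapC", "FapBC_repeat", 1e-20, 55, 110, 161, idx = 2, of = 3),
    dom_line("fapC", "FapBC_repeat", 1e-20, 60, 45, 96, idx = 1, of = 3),
    dom_line("fapC", "FapBC_repeat", 1e-20, 50, 173, 211, idx = 3, of = 3)))
  hits <- parse_domtblout(path)
  reps <- count_repeats("fapC", hits)
  expect_equal(reps$ir_index, 1:3)
  expect_equal(reps$start_aa, c(45L, 110L, 173L))
  expect_equal(reps$end_aa, c(96L, 161L, 211L))

  # no domains -> empty
  expect_equal(nrow(count_repeats("other", hits)), 0)

  # 74% overlap of the shorter domain: keep the higher-scoring one
  ov <- parse_domtblout(write_dom(c(
    dom_line("gO", "FapBC_repeat", 1e-20, 40, 10, 48),
    dom_line("gO", "FapBC_repeat", 1e-20, 60, 20, 58, idx = 2, of = 2))))
  res <- count_repeats("gO", ov)
  expect_equal(nrow(res), 1)
  expect_equal(res$start_aa, 20L)
  # brute-force check: every surviving pair overlaps by <= 50% of the shorter
  check_pairs <- function(r) {
    if (nrow(r) < 2) return(TRUE)
    all(apply(utils::combn(nrow(r), 2), 2, function(ij) {
      i <- ij[1]; j <- ij[2]
      inter <- min(r$end_aa[i], r$end_aa[j]) -
        max(r$start_aa[i], r$start_aa[j]) + 1
      shorter <- min(r$end_aa[i] - r$start_aa[i],
                     r$end_aa[j] - r$start_aa[j]) + 1
      inter <= 0.5 * shorter
    }))
  }
  expect_true(check_pairs(reps))
  expect_true(check_pairs(res))

  # repeat sequences can be pulled from the protein
  prot <- paste(rep("A", 250), collapse = "")
  with_seq <- count_repeats("fapC", hits, protein = prot)
  expect_equal(nchar(with_seq$sequence), c(52L, 52L, 39L))
})

test_that("census histogram totals are conserved", {
  synth <- synth_fap_genome(list(n_operons = 5), seed = 10)
  mined <- mine_fap_operons(synth$domtblout_path, synth$genes_path)
  cen <- mined$census
  expect_equal(sum(cen$genes_per_cluster), length(mined$operons))
  expect_equal(sum(cen$fapBC_per_cluster), length(mined$operons))
  expect_equal(sum(cen$repeats_per_fapC),
               sum(!is.na(sapply(mined$operons, function(o) o$fapC_gene_id))))
  expect_equal(operon_census(list(), list())$n_operons, 0)
})

test_that("mining output tables are written and readable", {
  synth <- synth_fap_genome(list(n_operons = 3), seed = 4)
  mined <- mine_fap_operons(synth$domtblout_path, synth$genes_path)
  dir <- withr::local_tempdir()
  write_mining_tables(mined, dir)
  op <- read.delim(file.path(dir, "operons.tsv"))
  expect_equal(nrow(op), 3)
  expect_true(file.exists(file.path(dir, "census_repeats_per_fapC.tsv")))
})
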