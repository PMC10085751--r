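test_that("reverse complement is the standard involution", {
  expect_equal(reverse_complement("ACG"), "CGT")
  expect_equal(reverse_complement("N"), "N")
  expect_error(reverse_complement("ACX"), "illegal")
  set.seed(42)
  for (i in 1:20) {
    s <- random_genome(sample(1:30, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
  # brute force over the full keyspaces: no odd-length k-mer can be its
  # own reverse complement (the center base would have to self-pair),
  # while exactly 16 of the 256 4-mers are revcomp-invariant
  k3 <- contextmut:::kmer_keyspace(3)
  expect_equal(sum(vapply(k3, oracle_revcomp, "") == k3), 0L)
  k4 <- contextmut:::kmer_keyspace(4)
  expect_equal(sum(vapply(k4, oracle_revcomp, "") == k4), 16L)
})

test_that("context counting handles wrap-around and tiny cases by hand", {
  g <- cdm_genome("g", "AAAA", circular = TRUE)
  ct <- count_contexts(g, NULL, 3, "genome", "reference")
  expect_equal(unname(ct$counts[["AAA"]]), 4L)
  expect_equal(sum(ct$counts), 4L)

  g2 <- cdm_genome("g", "ACGT", circular = TRUE)
  ct2 <- count_contexts(g2, NULL, 3, "genome", "reference")
  expect_equal(unname(ct2$counts[c("ACG", "CGT", "GTA", "TAC")]),
               rep(1L, 4))
  ct2c <- count_contexts(g2, NULL, 3, "genome", "complement")
  for (t in c("ACG", "CGT", "GTA", "TAC"))
    expect_equal(unname(ct2c$counts[[oracle_revcomp(t)]]),
                 unname(ct2$counts[[t]]))

  lin <- cdm_genome("g", "ACGTT", circular = FALSE)
  ctl <- count_contexts(lin, NULL, 3, "genome", "reference")
  expect_equal(sum(ctl$counts), 3L)  # L - k + 1

  expect_error(count_contexts(cdm_genome("g", "ACG"), NULL, 5), "length")
})

test_that("windows containing N are tallied as skipped, never dropped", {
  g <- cdm_genome("g", "ACGNACGT", circular = TRUE)
  ct <- count_contexts(g, NULL, 3, "genome", "reference")
  expect_equal(sum(ct$counts) + ct$n_skipped, 8L)
  expect_equal(ct$n_skipped, 3L)  # windows with center 3,4,5 contain N
})

test_that("context counts equal a naive slicing oracle on random genomes", {
  for (seed in 1:10) {
    set.seed(seed)
    L <- sample(200:800, 1)
    circular <- seed %% 2 == 0
    s <- random_genome(L, stats::runif(1, 0.3, 0.7))
    g <- cdm_genome("g", s, circular = circular)
    ori <- sample(L, 1)
    ter <- sample(setdiff(seq_len(L), ori), 1)
    fr <- replication_frame(ori, ter, L, circular = circular)
    for (k in c(3, 4, 5)) for (region in c("genome", "right_replichore"))
      for (strand in c("reference", "complement")) {
        got <- count_contexts(g, fr, k, region, strand)
        ora <- oracle_count_contexts(s, circular, k, ori, ter, region,
                                     strand)
        nz <- got$counts[got$counts > 0]
        expect_equal(nz[sort(names(nz))],
                     ora$counts[sort(names(ora$counts))],
                     label = sprintf("seed %d k %d %s %s", seed, k,
                                     region, strand))
        expect_equal(got$n_skipped, ora$n_skipped)
      }
  }
})

test_that("replichore counts add up to the chromosome counts key by key", {
  for (seed in 1:5) {
    g <- generate_genome(1000L, 0.5, seed = seed)$genome
    fr <- replication_frame(sample(1000L, 1),
                            sample(setdiff(1:1000, 1), 1), 1000L)
    gw <- count_contexts(g, fr, 3, "genome", "reference")
    rr <- count_contexts(g, fr, 3, "right_replichore", "reference")
    lr <- count_contexts(g, fr, 3, "left_replichore", "reference")
    expect_identical(rr$counts + lr$counts, gw$counts)
    expect_equal(sum(gw$counts), 1000L)
  }
})

test_that("variant context extraction matches the documented examples", {
  g <- cdm_genome("g", "TACGT", circular = FALSE)
  fr <- replication_frame(1L, 3L, 5L, circular = FALSE)
  v <- data.frame(position = 3L, ref = "C", alt = "T")
  # position 3 is on the left replichore here? ori=1,ter=3: right=[1,3)
  # so position 3 is left; as-reference read
  res <- extract_context(g, fr, v, "as_reference")
  expect_equal(res$contexts$up_base, "A")
  expect_equal(res$contexts$down_base, "G")
  expect_equal(res$contexts$oriented_triplet, "ACG")
  expect_equal(res$contexts$replichore, "left")
  # the same site placed on the right replichore under the
  # lagging-template convention is read in reverse complement
  fr2 <- replication_frame(2L, 5L, 5L, circular = FALSE)
  res2 <- extract_context(g, fr2, v, "lagging_template_revcomp")
  expect_equal(res2$contexts$replichore, "right")
  expect_equal(res2$contexts$oriented_triplet, "CGT")
  expect_equal(res2$contexts$oriented_ref, "G")
  expect_equal(res2$contexts$oriented_alt, "A")
})

test_that("terminal and ambiguous contexts are excluded with reasons", {
  lin <- cdm_genome("g", "ACGTA", circular = FALSE)
  fr <- replication_frame(1L, 3L, 5L, circular = FALSE)
  v <- data.frame(position = c(1L, 3L, 5L), ref = c("A", "G", "A"),
                  alt = c("G", "A", "C"))
  res <- extract_context(lin, fr, v, "as_reference")
  expect_equal(nrow(res$contexts), 1L)
  expect_equal(sort(res$exclusion_log$reason),
               rep("terminal position on linear genome", 2))

  gn <- cdm_genome("g", "ANGTA", circular = TRUE)
  vn <- data.frame(position = 3L, ref = "G", alt = "A")
  resn <- extract_context(gn, fr, vn, "as_reference")
  expect_equal(resn$exclusion_log$reason, "ambiguous context")
})

test_that("oriented triplets match a brute-force recomputation", {
  st <- generate_study(withr::local_tempdir(), length = 3000,
                       u_true = test_u_true(), G = 5077, N = 50,
                       seed = 21L)
  L <- st$genome$length
  fr <- replication_frame(101L, 1601L, L)
  res <- extract_context(st$genome, fr, st$variants,
                         "lagging_template_revcomp")
  expect_gt(nrow(res$contexts), 50)
  for (i in seq_len(nrow(res$contexts))) {
    row <- res$contexts[i, ]
    ora <- oracle_context(st$genome$sequence, TRUE, row$position,
                          row$ref, row$alt, 101L, 1601L)
    expect_equal(row$oriented_triplet, ora$triplet)
    expect_equal(row$oriented_ref, ora$ref)
    expect_equal(row$oriented_alt, ora$alt)
    expect_equal(row$replichore, ora$replichore)
  }
})

test_that("context extraction is local to the k-window", {
  s <- random_genome(100, 0.5, seed = 31)
  g <- cdm_genome("g", s)
  fr <- replication_frame(1L, 51L, 100L)
  v <- data.frame(position = 40L, ref = substr(s, 40, 40), alt = "A")
  if (v$ref == "A") v$alt <- "C"
  before <- extract_context(g, fr, v, "as_reference")$contexts
  # mutate the genome far outside the window
  s2 <- paste0(substr(s, 1, 69), "T", substr(s, 71, 100))
  g2 <- cdm_genome("g", s2)
  after <- extract_context(g2, fr, v, "as_reference")$contexts
  expect_identical(before, after)
})

test_that("codon usage tallies in-frame codons with strand symmetry", {
  g <- cdm_genome("g", "ATGAAATAAC")
  ann <- data.frame(start = 1L, end = 9L, strand = "+", kind = "CDS",
                    locus_tag = "c1", partial = FALSE, compound = FALSE,
                    stringsAsFactors = FALSE)
  ann$segments <- list(matrix(c(1L, 9L), 1, 2))
  class(ann) <- c("cdm_annotation", "data.frame")
  cu <- count_codon_usage(g, ann)
  expect_equal(unname(cu$counts[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_equal(sum(cu$counts), 3L)

  # the same CDS annotated on the minus strand of the revcomp sequence
  g2 <- cdm_genome("g2", paste0(reverse_complement("ATGAAATAA"), "C"))
  ann2 <- ann
  ann2$strand <- "-"
  cu2 <- count_codon_usage(g2, ann2)
  expect_identical(cu2$counts, cu$counts)
})

test_that("fixture codon manifests agree with the codon counter", {
  g <- generate_genome(4000L, 0.5, seed = 13L)$genome
  a <- generate_annotations(g, 10L, seed = 13L)
  cu <- count_codon_usage(g, a$annotations)
  expect_identical(as.list(cu$counts), a$manifest$codon_tallies)
  # per-replichore split covers every CDS exactly once
  fr <- replication_frame(1L, 2001L, 4000L)
  cur <- count_codon_usage(g, a$annotations, fr, "right_replichore")
  cul <- count_codon_usage(g, a$annotations, fr, "left_replichore")
  expect_identical(cur$counts + cul$counts, cu$counts)
})
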