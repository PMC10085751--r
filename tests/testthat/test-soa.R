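# one shared fixture study for the pipeline tests
local_study <- function(dir, seed = 91L, id = "bsub_like") {
  generate_study(file.path(dir, paste0("fx", seed)), length = 6000,
                 gc_fraction = 0.44, n_cds = 10, u_true = test_u_true(),
                 G = 5077, N = 50, seed = seed, id = id)
}

test_that("the full single-organism pipeline completes and logs G and N", {
  dir <- withr::local_tempdir()
  st <- local_study(dir)
  cfg <- soa_config(st$fasta, st$genbank, st$basecall,
                    dialect = "basecall", generations = 5077,
                    lineages = 50, scaling = "0", ori = 0, ter = 3001,
                    out = file.path(dir, "out"), run_id = "wt",
                    figures = TRUE)
  run <- run_soa(cfg)
  expect_equal(run$log$generations, 5077)
  expect_equal(run$log$lineages, 50L)
  expect_equal(run$frame$ori, 1L)          # "0" normalised to 1
  expect_equal(run$frame$ter, 3001L)
  expect_equal(run$frame$source, "user")
  log <- jsonlite::fromJSON(file.path(run$out_dir, "run_log.json"))
  expect_equal(log$generations, 5077)
  expect_equal(log$lineages, 50)
  # filtering-step accounting
  expect_equal(log$n_candidates, log$n_retained + log$n_excluded_load)
  # every rates CSV carries the full 192-class table
  for (f in list.files(file.path(run$out_dir, "rates"),
                       pattern = "^rates_", full.names = TRUE))
    expect_equal(nrow(read_rates_csv(f)), 192L)
  expect_true(file.exists(file.path(run$out_dir, "figures",
                                    "rate_heatmap.png")))
})

test_that("validation fails before any compute on missing inputs", {
  dir <- withr::local_tempdir()
  st <- local_study(dir, seed = 92L)
  expect_error(soa_config("/nonexistent.fasta", st$genbank, st$basecall,
                          dialect = "basecall", generations = 10,
                          lineages = 5),
               "does not exist")
  expect_error(soa_config(st$fasta, st$genbank, st$basecall,
                          dialect = "basecall", generations = 10,
                          lineages = 5, run_id = "bad/id"),
               "filesystem-safe")
  expect_error(soa_config(st$fasta, st$genbank, st$basecall,
                          dialect = "basecall", generations = 10,
                          lineages = 5, ori = 5, ter = NULL),
               "both")
})

test_that("identical configurations produce byte-identical outputs", {
  dir <- withr::local_tempdir()
  st <- local_study(dir, seed = 93L)
  mk <- function(root) soa_config(
    st$fasta, st$genbank, st$vcf, dialect = "vcf", generations = 5077,
    lineages = 50, scaling = "0", ori = 1, ter = 3001,
    out = file.path(dir, root), run_id = "wt", figures = FALSE)
  r1 <- run_soa(mk("out_a"))
  r2 <- run_soa(mk("out_b"))
  files1 <- list.files(r1$out_dir, recursive = TRUE)
  files2 <- list.files(r2$out_dir, recursive = TRUE)
  expect_identical(files1, files2)
  text_files <- files1[grepl("\\.(csv|json)$", files1)]
  expect_gt(length(text_files), 10)
  for (f in text_files) {
    expect_identical(readLines(file.path(r1$out_dir, f)),
                     readLines(file.path(r2$out_dir, f)),
                     label = f)
  }
})

test_that("prompt-style answers reproduce the flag configuration", {
  dir <- withr::local_tempdir()
  st <- local_study(dir, seed = 94L)
  answers <- c("Bacillus_like_WT", "basecall", st$fasta, st$genbank,
               st$basecall, "5077", "50", "0", "yes", "0", "3001")
  cfg_prompt <- soa_config_from_answers(answers,
                                        out = file.path(dir, "out"))
  cfg_flags <- soa_config(st$fasta, st$genbank, st$basecall,
                          dialect = "basecall", generations = 5077,
                          lineages = 50, scaling = "0", ori = 1,
                          ter = 3001, out = file.path(dir, "out"),
                          run_id = "Bacillus_like_WT")
  expect_identical(cfg_prompt, cfg_flags)
  expect_equal(cfg_prompt$params$ori_override, 1L)  # "0" -> position 1
})

test_that("auto-detection kicks in when no ORI/TER are supplied", {
  dir <- withr::local_tempdir()
  seed <- 95L
  stdir <- file.path(dir, "fx")
  # no CDS in the annotation: detection falls back to all-site skew,
  # which pins the planted switch points
  st <- generate_study(stdir, length = 6000, gc_fraction = 0.44,
                       skew = list(ori_target = 500L, ter_target = 3500L,
                                   skew_strength = 1),
                       n_cds = 0,
                       u_true = list(AAA = c(G = 1e-6),
                                     TTT = c(C = 1e-6)),
                       G = 5077, N = 50, seed = seed)
  cfg <- soa_config(st$fasta, st$genbank, st$basecall,
                    dialect = "basecall", generations = 5077,
                    lineages = 50, out = file.path(dir, "out"),
                    run_id = "auto", figures = FALSE)
  run <- run_soa(cfg)
  expect_equal(run$frame$source, "oriloc_like")
  expect_lte(circ_dist(run$frame$ori, 500L, 6000L), 1)
  expect_lte(circ_dist(run$frame$ter, 3500L, 6000L), 1)
  expect_equal(assign_replichore(run$frame, 2000L), "right")
})

test_that("multi-organism analysis correlates, sorts and renders", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "out")
  for (s in c(96L, 97L, 98L)) {
    st <- local_study(dir, seed = s, id = paste0("org", s))
    run_soa(soa_config(st$fasta, st$genbank, st$vcf, dialect = "vcf",
                       generations = 5077, lineages = 50, ori = 1,
                       ter = 3001, out = out,
                       run_id = paste0("org", s), figures = FALSE))
  }
  tab <- run_moa(out, basis = "chromosome", figures = TRUE)
  expect_equal(sort(tab$row_order), c("org96", "org97", "org98"))
  m <- build_correlation_grid(tab)
  expect_true(all(abs(m[cbind(tab$row_order, tab$row_order)] - 1)
                  < 1e-12))
  # same planted rate map in every organism: strong correlations
  expect_true(all(m > 0.8))
  expect_true(file.exists(file.path(out, "moa",
                                    "correlation_pairs.csv")))
  expect_true(file.exists(file.path(out, "moa",
                                    "correlation_heatmap.png")))
  # replichore and strand bases also work
  expect_s3_class(run_moa(out, basis = "replichore", figures = FALSE),
                  "cdm_correlation")

  # fewer than two runs is an explicit error
  expect_error(run_moa(withr::local_tempdir()), "at least 2")
})
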