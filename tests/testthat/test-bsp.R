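test_that("clone calling reproduces the hand-enumerated 11-mer example", {
  ref <- amplicon("amp", "ACGTTCAACGA")
  expect_equal(ref$cpg_positions, c(1L, 8L))
  cc <- call_clone(ref, "ATGTTTAACGA")
  # CpG@1 read T -> unmethylated; CpG@8 read C -> methylated;
  # the single non-CpG C (position 5) read T -> conversion 1/1
  expect_equal(unname(cc$calls), c("unmethylated", "methylated"))
  expect_equal(cc$conversion_rate, 1)
  expect_true(cc$passed_qc)
})

test_that("unconverted and fully converted clones behave at the extremes", {
  ref <- amplicon("amp", "ACGTTCAACGA")
  same <- call_clone(ref, ref$seq)          # identical to reference
  expect_true(all(same$calls == "methylated"))
  expect_equal(same$conversion_rate, 0)
  expect_false(same$passed_qc)

  conv <- chartr("C", "T", ref$seq)         # every C -> T
  full <- call_clone(ref, conv)
  expect_true(all(full$calls == "unmethylated"))
  expect_equal(full$conversion_rate, 1)

  # determinism / idempotence
  expect_identical(call_clone(ref, conv), call_clone(ref, conv))
})

test_that("indel clones are aligned bisulfite-aware before calling", {
  ref <- amplicon("amp", "ACGTTCAACGAACCGTT")
  # fully converted clone with a 2-bp deletion in the middle
  clone <- chartr("C", "T", ref$seq)
  clone <- paste0(substr(clone, 1, 6), substr(clone, 9, nchar(clone)))
  cc <- call_clone(ref, clone)
  expect_equal(length(cc$calls), length(ref$cpg_positions))
  expect_true(all(cc$calls %in% c("methylated", "unmethylated", "ambiguous")))
  expect_error(call_clone(ref, clone, align = FALSE), "length")
})

test_that("ambiguous bases at CpGs are excluded from sample rates", {
  ref <- amplicon("amp", "TTCGTTCGTTCATT")   # CpGs at 2 and 6, non-CpG C at 11
  mk <- function(b1, b2) {
    s <- chartr("C", "T", ref$seq)           # converts all Cs incl. CpGs
    substr(s, 3, 3) <- b1
    substr(s, 7, 7) <- b2
    s
  }
  calls <- list(call_clone(ref, mk("C", "C"), "c1"),
                call_clone(ref, mk("C", "T"), "c2"),
                call_clone(ref, mk("G", "T"), "c3"))   # one ambiguous call
  expect_warning(ss <- sample_summary(calls, "s1", "tumor", min_clones = 10),
                 "only 3")
  # calls: c1 M,M; c2 M,U; c3 ?,U  -> 3 methylated / 5 informative
  expect_equal(ss$rate, 3 / 5)
  expect_equal(ss$n_clones, 3L)
  expect_equal(unname(ss$per_site_rates), c(2 / 2, 1 / 3))
})

test_that("lollipop export has passing clones as rows and 1/0/? entries", {
  ref <- amplicon("amp", "TTCGTTCGTT")
  unconv <- call_clone(ref, ref$seq, "bad")      # no non-CpG C -> conv NA
  conv <- call_clone(ref, chartr("C", "T", ref$seq), "good")
  # amplicon without non-CpG C: conversion undefined, clone fails QC
  expect_false(unconv$passed_qc)
  m <- clone_matrix(list(unconv, conv), passing_only = FALSE)
  expect_equal(dim(m), c(2L, 2L))
  expect_true(all(m %in% c("1", "0", "?")))
  expect_equal(unname(m["good", ]), c("0", "0"))
})

test_that("ten fully methylated clones give rate 1; QC drops failing clones from the rate", {
  cfg <- sim_config(seed = 3)
  sim <- gen_bsp(cfg, n_cpg = 10)
  ref <- sim$ref
  meth_clone <- local({                  # methylated at CpGs, converted elsewhere
    ch <- strsplit(ref$seq, "")[[1]]
    ncc <- setdiff(which(ch == "C"), ref$cpg_positions + 1L)
    ch[ncc] <- "T"
    paste(ch, collapse = "")
  })
  calls <- lapply(1:10, function(i) call_clone(ref, meth_clone, paste0("c", i)))
  ss <- sample_summary(calls, "s", "tumor")
  expect_equal(ss$rate, 1.0)
  expect_equal(ss$n_clones, 10L)

  # 4 passing + 6 unconverted clones: rate over the 4, with a warning
  calls2 <- c(calls[1:4],
              lapply(5:10, function(i) call_clone(ref, ref$seq, paste0("u", i))))
  expect_warning(ss2 <- sample_summary(calls2, "s2", "tumor"), "only 4")
  expect_equal(ss2$n_clones, 4L)
  expect_equal(ss2$rate, 1.0)

  expect_error(sample_summary(list(call_clone(ref, ref$seq)), "s3"), "QC")
})

test_that("simulated clones recover the per-CpG methylation probability", {
  cfg <- sim_config(seed = 29, conversion_eff = 1)
  sim <- gen_bsp(cfg, n_cpg = 20)
  ref <- sim$ref
  p <- 0.361
  set.seed(71)
  n_clones <- 1000L
  cpos <- ref$cpg_positions + 1L
  calls <- lapply(seq_len(n_clones), function(k) {
    ch <- strsplit(ref$seq, "")[[1]]
    meth <- runif(length(cpos)) < p
    ch[cpos[!meth]] <- "T"
    ncc <- setdiff(which(ch == "C"), cpos)
    ch[ncc] <- "T"
    call_clone(ref, paste(ch, collapse = ""), paste0("c", k))
  })
  ss <- sample_summary(calls, "big", "tumor", min_clones = 10)
  n_calls <- n_clones * length(cpos)
  ci <- p + c(-1.96, 1.96) * sqrt(p * (1 - p) / n_calls)
  expect_gte(ss$rate, ci[1])
  expect_lte(ss$rate, ci[2])
})

test_that("group comparison: identical rates give p 1; complete separation matches enumeration; paired shift is detected", {
  same <- data.frame(rate = rep(c(0.2, 0.3, 0.4), 2),
                     group = rep(c("tumor", "normal"), each = 3))
  expect_equal(compare_groups(same)$p, 1)

  sep <- data.frame(rate = c(6:10 / 10, 1:5 / 100),
                    group = rep(c("tumor", "normal"), each = 5))
  expect_equal(compare_groups(sep)$p, 2 / 252)
  expect_equal(compare_groups(sep)$p,
               oracle_mw_exact_p(6:10 / 10, 1:5 / 100))

  set.seed(37)                     # paired 18 vs 18 with planted shift 0.30
  nor <- runif(18, 0.01, 0.15)
  tum <- pmin(nor + 0.30 + rnorm(18, 0, 0.05), 1)
  paired <- data.frame(rate = c(tum, nor),
                       group = rep(c("tumor", "normal"), each = 18))
  expect_lt(compare_groups(paired, paired = TRUE)$p, 0.001)
})

test_that("half-efficiency conversion fails QC for about half the clones", {
  cfg <- sim_config(seed = 59, conversion_eff = 0.5, n_bsp_pairs = 5L)
  sim <- gen_bsp(cfg, n_cpg = 10)
  all_pass <- unlist(lapply(names(sim$clones), function(s) {
    vapply(names(sim$clones[[s]]), function(cid) {
      call_clone(sim$ref, sim$clones[[s]][[cid]])$passed_qc
    }, logical(1))
  }))
  # with ~20+ non-CpG Cs per clone, P(conversion >= 0.95 | eff 0.5) is tiny
  expect_lt(mean(all_pass), 0.2)
})
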