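beta_mat <- function(mat, groups) {
  rownames(mat) <- sprintf("cg%07d", seq_len(nrow(mat)))
  colnames(mat) <- sprintf("s%03d", seq_len(ncol(mat)))
  list(mat = mat, group = groups)
}

test_that("per-probe screen computes delta-beta, skips sparse probes, flags directions", {
  m <- rbind(c(0.8, 0.8, 0.2, 0.2),
             c(0.5, 0.5, 0.5, 0.5),
             c(NA, 0.9, 0.1, 0.2))          # only 1 tumor value -> skipped
  bm <- beta_mat(m, c("tumor", "tumor", "normal", "normal"))
  dm <- probe_dm(bm$mat, bm$group)
  expect_equal(nrow(dm), 2L)
  expect_equal(dm$delta_beta[1], 0.6)
  expect_equal(dm$delta_beta[2], 0)
  expect_equal(dm$direction[2], "ns")
  expect_equal(attr(dm, "skipped"), "cg0000003")
  expect_true(all(dm$fdr >= dm$p))

  expect_error(probe_dm(bm$mat * 2, bm$group), "\\[0,1\\]")
})

test_that("probe screen p-values are invariant to monotone transforms of beta", {
  set.seed(31)
  m <- matrix(rbeta(30 * 10, 2, 2), 30, 10)
  bm <- beta_mat(m, rep(c("tumor", "normal"), each = 5))
  p1 <- probe_dm(bm$mat, bm$group)$p
  p2 <- probe_dm(bm$mat^2, bm$group)$p     # x^2 is monotone on [0,1]
  expect_equal(p1, p2)
})

test_that("planted promoter shifts are recovered; delta-beta matches the planted sign", {
  cfg <- sim_config(seed = 13, n_tumor = 15, n_normal = 15,
                    n_genes = 60, n_probes = 400, frac_driver = 0.2)
  ann <- gen_annotation(cfg)
  meth <- gen_methylation(cfg, ann)
  dm <- probe_dm(meth$beta, meth$group)
  planted <- meth$truth_probes[meth$truth_probes$planted, ]
  got <- dm[match(planted$probe_id, dm$probe_id), ]
  expect_gte(mean(got$direction == planted$planted_direction), 0.9)
  expect_equal(sign(got$delta_beta), sign(planted$planted_delta_beta))
})

test_that("DMR candidates equal the brute-force maximal-run oracle on a 20-probe toy", {
  set.seed(17)
  n <- 20L
  pos <- cumsum(sample(c(100L, 300L, 700L), n, TRUE))
  probes <- data.frame(probe_id = sprintf("cg%07d", 1:n), chrom = "chr1",
                       pos = pos, strand = "+", stringsAsFactors = FALSE)
  # construct betas with known delta by giving both groups constant values
  delta <- round(runif(n, -0.4, 0.4), 2)
  normal <- matrix(0.5, n, 4)
  tumor <- matrix(0.5 + delta, n, 4)
  bm <- beta_mat(cbind(tumor, normal), rep(c("tumor", "normal"), each = 4))
  got <- find_dmrs(bm$mat, bm$group, probes, cutoff = 0.2, min_probes = 2,
                   resamples = 10, seed = 1)
  # oracle works from the observed group-mean difference, like the caller
  delta <- rowMeans(bm$mat[, 1:4]) - rowMeans(bm$mat[, 5:8])
  runs <- oracle_dmr_runs(delta, pos, 0.2, 2L, 500L)
  expect_equal(nrow(got), length(runs))
  got <- got[order(got$start), , drop = FALSE]
  runs <- runs[order(vapply(runs, function(r) pos[r[1]], numeric(1)))]
  for (k in seq_along(runs)) {
    expect_equal(got$start[k], min(pos[runs[[k]]]))
    expect_equal(got$end[k], max(pos[runs[[k]]]) + 1L)
    expect_equal(got$n_probes[k], length(runs[[k]]))
    expect_equal(got$area[k], sum(abs(delta[runs[[k]]])))
    # member probes share the sign of delta-beta
    expect_equal(length(unique(sign(delta[runs[[k]]]))), 1L)
  }
})

test_that("single isolated probes and sub-cutoff probes yield no DMR", {
  probes <- data.frame(probe_id = c("cg1", "cg2", "cg3"), chrom = "chr1",
                       pos = c(100L, 5000L, 10000L), strand = "+",
                       stringsAsFactors = FALSE)
  m <- rbind(c(0.9, 0.9, 0.3, 0.3),     # delta 0.6 but isolated
             c(0.55, 0.5, 0.45, 0.5),   # below cutoff
             c(0.5, 0.5, 0.5, 0.5))
  rownames(m) <- probes$probe_id
  colnames(m) <- paste0("s", 1:4)
  dmrs <- find_dmrs(m, rep(c("tumor", "normal"), each = 2), probes,
                    resamples = 5, seed = 3)
  expect_equal(nrow(dmrs), 0L)
})

test_that("planted 5-probe region is recovered with small empirical p; probe order does not matter", {
  set.seed(19)
  n_null <- 100L
  pos_null <- 2000L * seq_len(n_null)
  pos_plant <- max(pos_null) + 5000L + c(0L, 100L, 200L, 300L, 400L)
  probes <- data.frame(
    probe_id = sprintf("cg%07d", seq_len(n_null + 5L)),
    chrom = "chr1", pos = c(pos_null, pos_plant), strand = "+",
    stringsAsFactors = FALSE)
  grp <- rep(c("tumor", "normal"), each = 10)
  beta <- matrix(rbeta((n_null + 5) * 20, 2, 2), n_null + 5, 20)
  plant_rows <- n_null + (1:5)
  beta[plant_rows, grp == "tumor"] <- rbeta(5 * 10, 13, 7)    # mean 0.65
  beta[plant_rows, grp == "normal"] <- rbeta(5 * 10, 3, 17)   # mean 0.15
  rownames(beta) <- probes$probe_id
  colnames(beta) <- paste0("s", 1:20)
  dmrs <- find_dmrs(beta, grp, probes, resamples = 50, seed = 7)
  expect_gte(nrow(dmrs), 1L)
  top <- dmrs[1, ]
  expect_equal(top$start, pos_plant[1])
  expect_equal(top$end, pos_plant[5] + 1L)
  expect_lte(top$p_empirical, 0.05)

  # permuting probe row order leaves the result unchanged
  ord <- sample(nrow(beta))
  dmrs2 <- find_dmrs(beta[ord, ], grp, probes[ord, ], resamples = 50, seed = 7)
  expect_equal(dmrs2, dmrs)
})

test_that("more resamples changes p-values but not which regions are reported", {
  set.seed(23)
  probes <- data.frame(probe_id = sprintf("cg%07d", 1:10), chrom = "chr1",
                       pos = 100L * (1:10), strand = "+",
                       stringsAsFactors = FALSE)
  beta <- matrix(rbeta(10 * 12, 2, 2), 10, 12)
  beta[3:5, 1:6] <- rbeta(18, 16, 4)
  beta[3:5, 7:12] <- rbeta(18, 4, 16)
  rownames(beta) <- probes$probe_id; colnames(beta) <- paste0("s", 1:12)
  grp <- rep(c("tumor", "normal"), each = 6)
  a <- find_dmrs(beta, grp, probes, resamples = 20, seed = 5)
  b <- find_dmrs(beta, grp, probes, resamples = 40, seed = 5)
  expect_equal(a[, c("chrom", "start", "end", "n_probes", "area")],
               b[, c("chrom", "start", "end", "n_probes", "area")])
  # +1-smoothed empirical p stays in (0, 1]
  expect_true(all(a$p_empirical > 0 & a$p_empirical <= 1))
})
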