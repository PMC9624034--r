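test_that("manifest ingestion keeps rows, catches duplicates and bad coordinates", {
  d <- sim_tmpdir()
  f <- file.path(d, "man.tsv")
  writeLines(c("probe_id\tchrom\tpos\tstrand",
               "cg000001\tchr1\t100\t+",
               "cg000002\tchr1\t250\t-",
               "cg000003\tchr2\t5\t+"), f)
  m <- read_manifest(f)
  expect_equal(m$probe_id, c("cg000001", "cg000002", "cg000003"))
  expect_equal(m$pos, c(100L, 250L, 5L))

  writeLines(c("probe_id\tchrom\tpos\tstrand",
               "cg000001\tchr1\t100\t+",
               "cg000001\tchr1\t200\t+"), f)
  expect_error(read_manifest(f), "cg000001")

  writeLines(c("probe_id\tchrom\tpos\tstrand",
               "cg000001\tchr1\t10.5\t+"), f)
  expect_error(read_manifest(f), "row 1")

  writeLines(c("probe_id\tchrom\tpos\tstrand",
               "cg000009\tchr1\t100\t+"), f)
  expect_equal(read_manifest(f, one_based = TRUE)$pos, 99L)

  writeLines("probe_id\tchrom\tpos\tstrand", f)
  expect_equal(nrow(read_manifest(f)), 0L)

  writeLines(c("probe_id\tchrom\tpos", "cg1\tchr1\t3"), f)
  expect_error(read_manifest(f), "strand")
})

test_that("GTF transcripts are filtered by biotype and converted to 0-based half-open", {
  d <- sim_tmpdir()
  f <- file.path(d, "toy.gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t100\t200\t.\t+\t.\tgene_id "G1"; transcript_id "G1"; gene_type "lincRNA"; gene_name "N1";',
    'chr1\tsrc\ttranscript\t100\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; gene_type "lincRNA"; gene_name "N1";',
    'chr1\tsrc\ttranscript\t300\t500\t.\t-\t.\tgene_id "G1"; transcript_id "T2"; gene_type "lincRNA"; gene_name "N1";',
    'chr2\tsrc\ttranscript\t50\t80\t.\t+\t.\tgene_id "G2"; transcript_id "T3"; gene_type "protein_coding"; gene_name "N2";'),
    f)
  tx <- read_gtf_lnc(f, biotypes = "lincRNA")
  expect_equal(nrow(tx), 2L)                     # gene row and coding gene dropped
  expect_equal(tx$start[tx$transcript_id == "T1"], 99L)
  expect_equal(tx$end[tx$transcript_id == "T1"], 200L)
  expect_equal(unique(tx$gene_id), "G1")         # two transcripts share the gene

  expect_equal(nrow(read_gtf_lnc(f, biotypes = "antisense")), 0L)
})

test_that("promoter windows follow the -2500/+1000 strand-aware rule with clipping", {
  tx <- data.frame(gene_id = c("A", "B", "C"),
                   transcript_id = c("A.1", "B.1", "C.1"),
                   gene_name = NA, gene_type = "lincRNA",
                   chrom = "chr1",
                   start = c(5000L, 100L, 5000L),
                   end = c(9000L, 900L, 9000L),
                   strand = c("+", "+", "-"),
                   stringsAsFactors = FALSE)
  w <- promoter_windows(tx)
  expect_equal(unname(unlist(w[w$gene_id == "A", c("start", "end")])),
               c(2500L, 6000L))
  expect_equal(unname(unlist(w[w$gene_id == "B", c("start", "end")])),
               c(0L, 1100L))                     # clipped at the origin
  # minus strand: tss = 8999; window enumerated from strand-relative offsets
  expect_equal(w$tss[w$gene_id == "C"], 8999L)
  expect_equal(unname(unlist(w[w$gene_id == "C", c("start", "end")])),
               c(8000L, 11500L))
  expect_error(promoter_windows(tx, upstream = -1))
})

test_that("promoter windows have length upstream+downstream, contain the TSS, and are strand-flip symmetric", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 20L
    L <- 100000L
    start <- sample(5000:80000, n)
    tx <- data.frame(gene_id = sprintf("G%02d", 1:n),
                     transcript_id = sprintf("G%02d.1", 1:n),
                     gene_name = NA, gene_type = "lincRNA", chrom = "chr1",
                     start = start, end = start + sample(500:5000, n),
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
    w <- promoter_windows(tx)
    expect_true(all(w$end - w$start == 3500L))
    expect_true(all(w$tss >= w$start & w$tss < w$end))

    # reverse-complement the coordinate system: pos -> L-1-pos, strand flip
    flip <- tx
    flip$start <- L - tx$end
    flip$end <- L - tx$start
    flip$strand <- ifelse(tx$strand == "+", "-", "+")
    wf <- promoter_windows(flip)
    expect_equal(wf$start, L - w$end)
    expect_equal(wf$end, L - w$start)
    expect_equal(wf$tss, L - 1L - w$tss)
  }
})

test_that("probe-to-promoter join respects half-open boundaries and matches the brute-force scan", {
  probes <- data.frame(probe_id = c("p1", "p2"), chrom = "chr1",
                       pos = c(2500L, 6000L), strand = "+",
                       stringsAsFactors = FALSE)
  win <- data.frame(gene_id = "G", transcript_id = "G.1", chrom = "chr1",
                    start = 2500L, end = 6000L, strand = "+", tss = 5000L,
                    stringsAsFactors = FALSE)
  j <- join_probes_to_promoters(probes, win)
  expect_equal(j$probe_id, "p1")                 # 2500 in, 6000 out

  set.seed(7)
  for (rep in 1:5) {
    np <- sample(20:50, 1)
    nw <- sample(3:5, 1)
    probes <- data.frame(probe_id = sprintf("p%03d", 1:np),
                         chrom = sample(c("chr1", "chr2"), np, TRUE),
                         pos = sample(0:5000, np), strand = "+",
                         stringsAsFactors = FALSE)
    ws <- sample(0:4000, nw)
    win <- data.frame(gene_id = sprintf("g%02d", 1:nw),
                      transcript_id = sprintf("g%02d.1", 1:nw),
                      chrom = sample(c("chr1", "chr2"), nw, TRUE),
                      start = ws, end = ws + sample(200:2000, nw),
                      strand = "+", tss = ws, stringsAsFactors = FALSE)
    expect_equal(join_probes_to_promoters(probes, win),
                 oracle_join(probes, win))
  }
})

test_that("transcript-level join keeps per-transcript rows while gene-level dedups", {
  probes <- data.frame(probe_id = "p1", chrom = "chr1", pos = 500L,
                       strand = "+", stringsAsFactors = FALSE)
  win <- data.frame(gene_id = "G", transcript_id = c("G.1", "G.2"),
                    chrom = "chr1", start = c(0L, 400L),
                    end = c(1000L, 1400L), strand = "+", tss = c(0L, 400L),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(join_probes_to_promoters(probes, win, by = "gene")), 1L)
  expect_equal(nrow(join_probes_to_promoters(probes, win, by = "transcript")), 2L)
})
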