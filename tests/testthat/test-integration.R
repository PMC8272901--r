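test_that("DEG filtering and intersection follow the source rules", {
  fib <- data.table(gene_id = c("G1", "G2", "G3"), log2_fc = c(1, -2, 1),
                    p_value = c(0.001, 0.002, 0.2),
                    fdr = c(0.01, 0.04, 0.6))
  card <- data.table(gene_id = c("G2", "G3", "G4"), log2_fc = c(-1, 2, 1),
                     p_value = c(0.01, 0.3, 0.02), fdr = NA_real_)
  f <- filter_degs(fib, fdr_max = 0.05)
  expect_identical(f$gene_id, c("G1", "G2"))
  c2 <- filter_degs(card, p_max = 0.05)
  expect_identical(c2$gene_id, c("G2", "G4"))
  expect_identical(filter_and_intersect_degs(f, c2), "G2")
  expect_identical(filter_and_intersect_degs(f[0L], c2), character(0))
  # planted overlap of size k is recovered exactly
  set.seed(2)
  shared <- sprintf("S%02d", 1:7)
  a <- data.table(gene_id = c(shared, sprintf("A%02d", 1:20)))
  b <- data.table(gene_id = c(sprintf("B%02d", 1:15), shared))
  expect_identical(filter_and_intersect_degs(a, b), sort(shared))
})

test_that("qcr matches its formula, the oracle, and its invariances", {
  expect_equal(qcr(c(1, -1), c(1, -1))$qcr, 1)
  expect_equal(qcr(c(1, -1), c(-1, 1))$qcr, -1)
  expect_error(qcr(numeric(0), numeric(0)), "empty")
  # axis points are excluded from counts and the denominator
  r <- qcr(c(1, 0, -1), c(1, 5, -1))
  expect_identical(r$n_total, 2L)
  expect_equal(r$qcr, 1)
  set.seed(66)
  for (rep in 1:50) {
    n <- sample(3:50, 1)
    x <- sample(c(-2, -1, 1, 2), n, TRUE)
    y <- sample(c(-2, -1, 1, 2), n, TRUE)
    expect_equal(qcr(x, y)$qcr, oracle_qcr(x, y))
    # invariant under positive rescaling, sign flip negates
    expect_equal(qcr(3.7 * x, 0.2 * y)$qcr, qcr(x, y)$qcr)
    expect_equal(qcr(-x, y)$qcr, -qcr(x, y)$qcr)
  }
})

test_that("direction_concordance pairs tiles with DEGs", {
  tiles <- data.table(chrom = "chr1", start = c(100L, 300L),
                      end = c(200L, 400L), mean_diff = c(40, -35),
                      direction = c("hyper", "hypo"))
  assoc <- data.table(tile_id = c(1L, 1L, 2L), gene_id = c("G1", "G2",
                                                           "G1"))
  degs <- data.table(gene_id = c("G1", "G2"), log2_fc = c(-1.5, 2))
  dc <- direction_concordance(tiles, assoc, degs)
  expect_identical(nrow(dc$pairs), 3L)   # one point per (tile, gene) pair
  # pairs: (+40, -1.5) -> +/-, (+40, +2) -> +/+, (-35, -1.5) -> -/-
  expect_equal(dc$fractions[["+/-"]], 1 / 3)
  expect_equal(dc$fraction_inverse, 1 / 3)
  expect_equal(dc$qcr$qcr, 1 / 3)
  # single hyper tile -> single down DEG: fully inverse
  one <- direction_concordance(tiles[1L],
                               data.table(tile_id = 1L, gene_id = "G1"),
                               degs[1L])
  expect_equal(one$fraction_inverse, 1)
  expect_equal(one$qcr$qcr, -1)
})

test_that("lad_redistribute performs the GoL/LoL/MoL algebra", {
  dcm <- interval_track(data.table(chrom = "chr1", start = 0, end = 100))
  ctl <- interval_track(data.table(chrom = "chr1", start = 50, end = 150))
  r <- lad_redistribute(dcm, ctl)
  expect_identical(norm_iv(r$gol),
                   data.table(chrom = "chr1", start = 0L, end = 50L))
  expect_identical(norm_iv(r$lol),
                   data.table(chrom = "chr1", start = 100L, end = 150L))
  expect_identical(norm_iv(r$mol),
                   data.table(chrom = "chr1", start = 50L, end = 100L))
  same <- lad_redistribute(dcm, dcm)
  expect_identical(nrow(same$gol), 0L)
  expect_identical(nrow(same$lol), 0L)
  expect_identical(norm_iv(same$mol), norm_iv(dcm))
})

test_that("LAD base counts are conserved on random tracks", {
  set.seed(41)
  for (rep in 1:10) {
    dcm <- random_track(sample(10:60, 1))
    ctl <- random_track(sample(10:60, 1))
    r <- lad_redistribute(dcm, ctl)
    expect_equal(interval_bases(r$gol) + interval_bases(r$mol),
                 interval_bases(dcm))
    expect_equal(interval_bases(r$lol) + interval_bases(r$mol),
                 interval_bases(ctl))
  }
})

test_that("conserve_across_celltypes keeps/drops by fibroblast overlap", {
  r <- lad_redistribute(
    interval_track(data.table(chrom = "chr1", start = c(0, 200, 400),
                              end = c(100, 300, 500))),
    interval_track(data.table(chrom = "chr1", start = c(200, 400),
                              end = c(300, 500))))
  # gol = [0,100); mol = [200,300),[400,500)
  fib <- interval_track(data.table(chrom = "chr1",
                                   start = c(50, 299), end = c(60, 300)))
  k <- conserve_across_celltypes(r, fib)
  expect_identical(nrow(k$gol), 0L)        # inside a fibroblast LAD
  expect_identical(norm_iv(k$mol),         # 1 bp overlap is enough
                   data.table(chrom = "chr1", start = 200L, end = 300L))
  # random inputs equal a direct overlap oracle
  set.seed(19)
  for (rep in 1:5) {
    r2 <- lad_redistribute(random_track(30), random_track(30))
    fb <- random_track(20)
    k2 <- conserve_across_celltypes(r2, fb)
    ovl <- function(tr) sapply(seq_len(nrow(tr)), function(i)
      any(fb$chrom == tr$chrom[i] & fb$start < tr$end[i] &
            fb$end > tr$start[i]))
    if (nrow(r2$gol))
      expect_identical(norm_iv(k2$gol), norm_iv(r2$gol[!ovl(r2$gol)]))
    if (nrow(r2$mol))
      expect_identical(norm_iv(k2$mol), norm_iv(r2$mol[ovl(r2$mol)]))
    if (nrow(r2$lol))
      expect_identical(norm_iv(k2$lol), norm_iv(r2$lol[ovl(r2$lol)]))
  }
})

test_that("deg_lad_distance categorizes genes and builds the window OR", {
  redist <- lad_redistribute(
    interval_track(data.table(chrom = "chr1", start = c(1000000, 8000000),
                              end = c(1100000, 8100000))),
    interval_track(data.table(chrom = "chr1", start = 8000000,
                              end = 8100000)))
  # gol = [1e6,1.1e6); mol = [8e6,8.1e6)
  genes <- data.table(
    gene_id = c("inGol", "near", "far"), chrom = "chr1", strand = "+",
    start = c(1050000L, 2500000L, 5000000L),
    end = c(1060000L, 2510000L, 5010000L))
  genes[, `:=`(exon_starts = as.character(start),
               exon_ends = as.character(end),
               tss = start)]
  dl <- deg_lad_distance(genes[1:2], redist, window = 2e6,
                         background_genes = genes)
  pg <- dl$per_gene
  expect_identical(pg[gene_id == "inGol", category], "within_GoL")
  expect_identical(pg[gene_id == "inGol", distance], 0L)
  expect_identical(pg[gene_id == "near", category], "distal")
  expect_identical(pg[gene_id == "near", distance], 1400000L)  # < 2 Mb
  expect_identical(dl$or$a, 2L)   # both focal genes within the window
  expect_error(deg_lad_distance(genes,
                                structure(list(gol = redist$gol[0L],
                                               lol = redist$lol[0L],
                                               mol = redist$mol[0L]),
                                          class = "lad_redistribution")),
               "empty LAD")
})

test_that("hotspot_proximity computes nearest distances and is seeded", {
  bg <- data.table(chrom = "chr1", pos = seq(1000L, 100000L, by = 100L))
  tgt <- data.table(chrom = "chr1", pos = c(1000L, 5200L))
  q <- data.table(chrom = "chr1", pos = 5000L)
  pr <- hotspot_proximity(q, tgt, bg, mode = "density", seed = 3)
  expect_identical(pr$observed_distances, 200)
  idpr <- hotspot_proximity(tgt, tgt, bg, mode = "density", seed = 3)
  expect_true(all(idpr$observed_distances == 0))
  # bit-identical reproduction under the same seed
  a <- hotspot_proximity(q, tgt, bg, seed = 11)
  b <- hotspot_proximity(q, tgt, bg, seed = 11)
  expect_identical(a$background_distances, b$background_distances)
  expect_identical(a$p_value, b$p_value)
  c_ <- hotspot_proximity(q, tgt, bg, seed = 12)
  expect_false(identical(a$background_distances, c_$background_distances))
  expect_error(hotspot_proximity(q, bg, tgt), "smaller than")
  # binned mode: per-bin one-tailed Fisher table
  prb <- hotspot_proximity(data.table(chrom = "chr1",
                                      pos = c(1100L, 5300L, 70000L)),
                           tgt, bg, mode = "binned", seed = 5,
                           bins = c(0, 1000, 10000))
  expect_identical(nrow(prb$bins), 3L)  # Inf edge appended
  expect_identical(prb$bins$n_observed[1L], 2L)
  expect_true(all(prb$bins$p_value >= 0 & prb$bins$p_value <= 1))
})

test_that("proximity results serialize to TSV + JSON", {
  bg <- data.table(chrom = "chr1", pos = seq(1000L, 50000L, by = 50L))
  pr <- hotspot_proximity(bg[1:20], bg[30:60], bg, seed = 2)
  tsv <- tempfile(); js <- tempfile()
  write_proximity_result(pr, tsv, js)
  dt <- fread(tsv)
  expect_identical(nrow(dt), length(pr$observed_distances) +
                     length(pr$background_distances))
  meta <- jsonlite::read_json(js)
  expect_identical(meta$test, "wilcoxon_rank_sum")
  expect_identical(meta$seed, 2L)
})
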