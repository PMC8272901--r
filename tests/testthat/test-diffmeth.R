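mk_matrix <- function(meth, cov, families = "A") {
  n <- ncol(meth)
  ids <- paste0("s", seq_len(n))
  colnames(meth) <- ids; colnames(cov) <- ids
  structure(list(sites = data.table(chrom = rep("chr1", nrow(meth)),
                                    pos = seq_len(nrow(meth)) * 100L),
                 meth = meth, cov = cov,
                 samples = data.table(sample_id = ids, family = families,
                                      status = "control"),
                 min_cov = 5L),
            class = "united_matrix")
}

test_that("group_design validates groups", {
  expect_error(group_design("x", character(), "p"), "non-empty")
  expect_error(group_design("x", c("a", "b"), c("b", "c")), "overlap")
})

test_that("call_dmcpgs retains extreme separation with the right sign", {
  # controls ~ 5%, patients ~ 97.5% methylated
  meth <- matrix(c(2L, 0L, 40L, 38L), 1L)
  cov <- matrix(c(40L, 40L, 40L, 40L), 1L)
  um <- mk_matrix(meth, cov)
  d <- group_design("x", c("s1", "s2"), c("s3", "s4"))
  dm <- call_dmcpgs(um, d)
  expect_identical(nrow(dm), 1L)
  expect_gt(dm$meth_diff, 90)
  expect_lt(dm$meth_diff, 100)
  # identical distributions -> diff 0, never retained
  um0 <- mk_matrix(matrix(rep(20L, 4L), 1L), matrix(rep(40L, 4L), 1L))
  expect_identical(nrow(call_dmcpgs(um0, d)), 0L)
  expect_error(call_dmcpgs(um, group_design("x", "s1", "zz")), "absent")
})

test_that("the binomial LRT equals glm logistic regression exactly", {
  set.seed(21)
  for (rep in 1:10) {
    cov <- matrix(rpois(5, 30) + 1L, 1L)
    meth <- matrix(rbinom(5, cov, runif(1, 0.05, 0.95)), 1L)
    um <- mk_matrix(meth, cov)
    d <- group_design("x", c("s1", "s2"), c("s3", "s4", "s5"))
    dm <- call_dmcpgs(um, d, diff_cutoff = 0, q_cutoff = 1)
    g <- factor(c(0, 0, 1, 1, 1))
    fit <- stats::glm(cbind(as.vector(meth), as.vector(cov - meth)) ~ g,
                      family = stats::binomial())
    p_glm <- stats::anova(fit, test = "Chisq")$`Pr(>Chi)`[2L]
    expect_equal(dm$p_value, p_glm, tolerance = 1e-10)
  }
})

test_that("fisher fallback matches fisher.test on pooled counts", {
  meth <- matrix(c(3L, 30L), 1L); cov <- matrix(c(35L, 36L), 1L)
  um <- mk_matrix(meth, cov)
  d <- group_design("x", "s1", "s2")
  dm <- call_dmcpgs(um, d, diff_cutoff = 0, q_cutoff = 1, test = "fisher")
  ref <- stats::fisher.test(matrix(c(30L, 6L, 3L, 32L), 2L))$p.value
  expect_equal(dm$p_value, ref, tolerance = 1e-12)
})

test_that("cutoffs act monotonically on the number of DMCpGs", {
  w <- tiny_world()
  n30 <- nrow(call_dmcpgs(w$um$A, w$designs$A, diff_cutoff = 30))
  n40 <- nrow(call_dmcpgs(w$um$A, w$designs$A, diff_cutoff = 40))
  n_q <- nrow(call_dmcpgs(w$um$A, w$designs$A, q_cutoff = 0.001))
  expect_lte(n40, n30)
  expect_lte(n_q, n30)
  expect_identical(attr(call_dmcpgs(w$um$A, w$designs$A), "correction"),
                   "BH")
})

test_that("tile_dmrs implements extension, merging and ambiguity rules", {
  one <- data.table(chrom = "chr1", pos = 1000L, meth_diff = 40)
  t1 <- tile_dmrs(one)
  expect_identical(t1$tiles$end - t1$tiles$start, 100L)
  expect_true(t1$tiles$start < 999L & t1$tiles$end > 1000L)
  expect_identical(t1$tiles$direction, "hyper")
  expect_equal(t1$tiles$mean_diff, 40)

  two <- data.table(chrom = "chr1", pos = c(1000L, 1400L),
                    meth_diff = c(35, 45))
  t2 <- tile_dmrs(two)
  expect_identical(nrow(t2$tiles), 1L)           # gap 400 <= 500
  expect_equal(t2$tiles$mean_diff, 40)
  far <- data.table(chrom = "chr1", pos = c(1000L, 1600L),
                    meth_diff = c(35, 45))
  expect_identical(nrow(tile_dmrs(far)$tiles), 2L)  # gap 600 > 500

  amb <- data.table(chrom = "chr1", pos = c(1000L, 1200L),
                    meth_diff = c(35, -35))
  ta <- tile_dmrs(amb)
  expect_identical(nrow(ta$tiles), 0L)
  expect_identical(ta$n_ambiguous_removed, 1L)

  # extension clips at coordinate 0 and pushes the remainder right
  left <- tile_dmrs(data.table(chrom = "chr1", pos = 3L, meth_diff = 40))
  expect_identical(left$tiles$start, 0L)
  expect_identical(left$tiles$end, 100L)
})

test_that("tile_dmrs equals the single-linkage oracle on random sets", {
  set.seed(55)
  for (rep in 1:6) {
    n <- sample(30:120, 1)
    dm <- data.table(chrom = sample(c("chr1", "chr2"), n, TRUE),
                     pos = sample.int(50000L, n),
                     meth_diff = sample(c(-1, 1), n, TRUE) *
                       runif(n, 30, 80))
    dm <- unique(dm, by = c("chrom", "pos"))
    setorder(dm, chrom, pos)
    got <- tile_dmrs(dm)
    want <- oracle_tiles(dm)
    expect_identical(got$n_ambiguous_removed, want$n_ambiguous_removed)
    expect_equal(got$tiles[, .(chrom, start, end, n_dmcpgs)],
                 want$tiles[, .(chrom, start, end, n_dmcpgs)],
                 ignore_attr = TRUE)
    expect_equal(got$tiles$mean_diff, want$tiles$mean_diff)
    expect_true(all(got$tiles$end - got$tiles$start >= 100L))
  }
})

test_that("classify_tiles reproduces the membership truth table", {
  # one synthetic region per membership pattern of (all, A, C)
  mk_tile <- function(start, diff = 40) data.table(
    chrom = "chr1", start = start, end = start + 200L, n_dmcpgs = 2L,
    mean_diff = diff, direction = if (diff > 0) "hyper" else "hypo")
  pats <- list(A = c(FALSE, TRUE, FALSE), C = c(FALSE, FALSE, TRUE),
               AC = c(FALSE, TRUE, TRUE), all = c(TRUE, FALSE, FALSE),
               allA = c(TRUE, TRUE, FALSE), allC = c(TRUE, FALSE, TRUE),
               allAC = c(TRUE, TRUE, TRUE))
  starts <- seq(1000L, by = 10000L, length.out = length(pats))
  runs <- list(all = list(), A = list(), C = list())
  for (i in seq_along(pats)) {
    p <- pats[[i]]
    if (p[1]) runs$all[[length(runs$all) + 1L]] <- mk_tile(starts[i])
    if (p[2]) runs$A[[length(runs$A) + 1L]] <- mk_tile(starts[i] + 10L)
    if (p[3]) runs$C[[length(runs$C) + 1L]] <- mk_tile(starts[i] - 10L)
  }
  bind <- function(l) if (length(l)) rbindlist(l) else mk_tile(1L)[0L]
  # united matrices with data everywhere
  sites <- data.table(chrom = "chr1", pos = seq(900L, 80000L, by = 50L))
  mkum <- function() structure(
    list(sites = sites, meth = matrix(0L, nrow(sites), 2L,
                                      dimnames = list(NULL, c("a", "b"))),
         cov = matrix(10L, nrow(sites), 2L,
                      dimnames = list(NULL, c("a", "b"))),
         samples = data.table(sample_id = c("a", "b"), family = "A",
                              status = c("control", "patient")),
         min_cov = 5L), class = "united_matrix")
  cls <- classify_tiles(bind(runs$all), bind(runs$A), bind(runs$C),
                        mkum(), mkum())
  # expected category per pattern
  expected <- c(A = "familyA_specific", C = "familyC_specific",
                AC = "shared", all = "shared", allA = "familyA_specific",
                allC = "familyC_specific", allAC = "shared")
  for (i in seq_along(pats)) {
    got <- unique(cls[start >= starts[i] - 10L &
                        start <= starts[i] + 10L, category])
    expect_identical(got, unname(expected[names(pats)[i]]),
                     label = paste("pattern", names(pats)[i]))
  }
  # partition: every eligible tile gets exactly one category
  expect_true(all(cls$category %in% c("shared", "familyA_specific",
                                      "familyC_specific")))
})

test_that("classify_tiles drops tiles without united data in a family", {
  tile <- data.table(chrom = "chr1", start = 1000L, end = 1200L,
                     n_dmcpgs = 1L, mean_diff = 40, direction = "hyper")
  sites_in <- data.table(chrom = "chr1", pos = 1100L)
  sites_out <- data.table(chrom = "chr1", pos = 99999L)
  mkum <- function(sites) structure(
    list(sites = sites, meth = matrix(0L, nrow(sites), 2L),
         cov = matrix(10L, nrow(sites), 2L),
         samples = data.table(sample_id = c("a", "b"), family = "A",
                              status = c("control", "patient")),
         min_cov = 5L), class = "united_matrix")
  cls <- classify_tiles(tile[0L], tile, tile[0L], mkum(sites_in),
                        mkum(sites_out))
  expect_identical(nrow(cls), 0L)
  expect_identical(attr(cls, "n_ineligible"), 1L)
})

test_that("classify_persistence labels the eight classes", {
  mk <- function(start, dir) data.table(
    chrom = "chr1", start = start, end = start + 200L, n_dmcpgs = 2L,
    mean_diff = if (dir == "hyper") 40 else -40, direction = dir)
  fib <- rbindlist(list(mk(1000L, "hyper"), mk(5000L, "hyper"),
                        mk(9000L, "hypo")))
  ipsc <- rbindlist(list(mk(1050L, "hypo"),      # hyper->hypo (reversed)
                         mk(13000L, "hyper")))   # none->hyper
  sites <- data.table(chrom = "chr1", pos = seq(900L, 14000L, by = 40L))
  mkum <- function() structure(
    list(sites = sites, meth = matrix(0L, nrow(sites), 2L),
         cov = matrix(10L, nrow(sites), 2L),
         samples = data.table(sample_id = c("a", "b"), family = "A",
                              status = c("control", "patient")),
         min_cov = 5L), class = "united_matrix")
  pers <- classify_persistence(fib, ipsc, mkum(), mkum())
  lab <- function(s) pers[start == s, persistence]
  expect_identical(lab(1000L), "hyper->hypo")
  expect_identical(lab(5000L), "hyper->none")
  expect_identical(lab(9000L), "hypo->none")
  expect_identical(lab(13000L), "none->hyper")
  expect_false(any(pers$persistence == "none->none"))
})

test_that("tile invariants hold on the tiny world", {
  w <- tiny_world()
  for (nm in names(w$tiles)) {
    t <- w$tiles[[nm]]
    expect_true(all(t$end - t$start >= 100L))
    # each tile span contains at least its recorded member DMCpGs
    dm <- w$dm[[nm]]
    for (i in seq_len(nrow(t))) {
      n_in <- dm[chrom == t$chrom[i] & pos > t$start[i] &
                   pos <= t$end[i], .N]
      expect_gte(n_in, t$n_dmcpgs[i])
    }
    expect_true(all(t$direction == ifelse(t$mean_diff > 0, "hyper",
                                          "hypo")))
  }
})

test_that("dmcpg table round-trips through TSV", {
  w <- tiny_world()
  f <- tempfile()
  write_dmcpgs(w$dm$A, f)
  back <- read_dmcpgs(f)
  expect_equal(back$pos, w$dm$A$pos)
  expect_equal(back$meth_diff, w$dm$A$meth_diff, tolerance = 1e-9)
})
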