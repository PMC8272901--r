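utils::globalVariables(c(
  "dmr_id", "delta", "associated", "dmr_sign", "is_deg", "rate"
))

#' Simulation configuration
#'
#' The stated world of the synthetic cohort: two families with distinct
#' mutations (family A: 2 controls, 3 patients; family C: 2 controls,
#' 2 patients) plus one unrelated donor control; a 2 x 5 Mb toy genome with
#' 50,000 CpGs placed as a mixture of uniform background and clustered
#' islands; per-site baseline methylation ~ Beta(0.4, 0.4) (bimodal
#' methylome); read coverage ~ Poisson(30) per site; planted DMRs
#' (defaults: 100 family-A-specific, 100 family-C-specific, 50 shared) of
#' |delta| = 40 percent points with baselines kept intermediate so the
#' shift stays in [0, 1].
#'
#' @param genome named chromosome-length vector.
#' @param n_cpgs total CpG sites.
#' @param families list: per family, `n_controls` and `n_patients`.
#' @param n_donor_controls unrelated donor controls (family "none").
#' @param coverage_mean Poisson mean read coverage per CpG site.
#' @param baseline_beta shape parameters of the baseline-rate Beta.
#' @param n_dmrs named vector: planted DMR counts for familyA, familyC,
#'   shared.
#' @param dmr_delta planted effect size in percent points (absolute).
#' @param dmr_width_range planted span width range in bp.
#' @param dmr_cpg_spacing mean CpG spacing inside planted spans (bp).
#' @param island_frac fraction of non-planted CpGs placed in clustered
#'   islands (rest uniform).
#' @param family_offset_sd,family_offset_frac small per-family baseline
#'   offsets (SD on the rate scale; fraction of sites affected) so
#'   genome-wide methylation clusters by family.
#' @param rho probability that a DMR-associated DEG's expression change is
#'   signed opposite to the methylation change.
#' @param ipsc list: `enabled`, `retain_frac` (fraction of fibroblast DMRs
#'   persisting in iPSC), `flip_frac` (fraction of those with reversed
#'   sign).
#' @param seed master seed; all randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome = c(chr1 = 5000000L, chr2 = 5000000L),
                       n_cpgs = 50000L,
                       families = list(
                         A = list(n_controls = 2L, n_patients = 3L),
                         C = list(n_controls = 2L, n_patients = 2L)),
                       n_donor_controls = 1L,
                       coverage_mean = 30,
                       baseline_beta = c(0.4, 0.4),
                       n_dmrs = c(familyA = 100L, familyC = 100L,
                                  shared = 50L),
                       dmr_delta = 40,
                       dmr_width_range = c(400L, 800L),
                       dmr_cpg_spacing = 40,
                       island_frac = 0.5,
                       family_offset_sd = 0.03,
                       family_offset_frac = 0.05,
                       rho = 0.65,
                       ipsc = list(enabled = TRUE, retain_frac = 0.25,
                                   flip_frac = 0.2),
                       seed = 1L) {
  cfg <- list(genome = genome, n_cpgs = as.integer(n_cpgs),
              families = families,
              n_donor_controls = as.integer(n_donor_controls),
              coverage_mean = coverage_mean,
              baseline_beta = baseline_beta, n_dmrs = n_dmrs,
              dmr_delta = dmr_delta, dmr_width_range = dmr_width_range,
              dmr_cpg_spacing = dmr_cpg_spacing, island_frac = island_frac,
              family_offset_sd = family_offset_sd,
              family_offset_frac = family_offset_frac, rho = rho,
              ipsc = ipsc, seed = as.integer(seed))
  if (cfg$dmr_delta < 0 || cfg$dmr_delta > 100)
    stop("dmr_delta must be in [0, 100] percent points")
  if (cfg$seed >= 2^30) stop("seed too large")
  structure(cfg, class = "sim_config")
}

#' Sample-sheet skeleton of a config
#' @param cfg a `sim_config`.
#' @return data.table: sample_id, family, status.
#' @export
sim_samples <- function(cfg) {
  rows <- list()
  pid <- 0L; cid <- 0L
  for (fam in names(cfg$families)) {
    f <- cfg$families[[fam]]
    for (i in seq_len(f$n_controls)) {
      cid <- cid + 1L
      rows[[length(rows) + 1L]] <-
        data.table(sample_id = sprintf("C%d", cid), family = fam,
                   status = "control")
    }
    for (i in seq_len(f$n_patients)) {
      pid <- pid + 1L
      rows[[length(rows) + 1L]] <-
        data.table(sample_id = sprintf("P%d", pid), family = fam,
                   status = "patient")
    }
  }
  for (i in seq_len(cfg$n_donor_controls)) {
    cid <- cid + 1L
    rows[[length(rows) + 1L]] <-
      data.table(sample_id = sprintf("C%d", cid), family = "none",
                 status = "control")
  }
  rbindlist(rows)
}

# place disjoint planted spans; 0-based half-open, padded 2 kb apart
plant_dmr_spans <- function(cfg) {
  chroms <- names(cfg$genome)
  total <- sum(cfg$n_dmrs)
  if (total == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), dmr_id = character(),
                      category = character(), sign_ = numeric(),
                      delta = numeric()))
  cats <- rep(names(cfg$n_dmrs), cfg$n_dmrs)
  spans <- data.table(chrom = character(), start = integer(),
                      end = integer())
  out <- vector("list", total)
  pad <- 2000L
  for (i in seq_len(total)) {
    for (try in 1:1000) {
      ch <- sample(chroms, 1L, prob = cfg$genome / sum(cfg$genome))
      w <- sample(cfg$dmr_width_range[1L]:cfg$dmr_width_range[2L], 1L)
      s <- sample.int(cfg$genome[[ch]] - w - pad, 1L) + pad %/% 2L
      clash <- spans[chrom == ch & start < s + w + pad & end > s - pad]
      if (!nrow(clash)) break
    }
    row <- data.table(chrom = ch, start = as.integer(s),
                      end = as.integer(s + w))
    spans <- rbindlist(list(spans, row))
    out[[i]] <- row
  }
  dt <- rbindlist(out)
  dt[, dmr_id := sprintf("dmr%04d", .I)]
  dt[, category := cats]
  dt[, sign_ := sample(c(1, -1), .N, replace = TRUE)]
  dt[, delta := cfg$dmr_delta]
  setorder(dt, chrom, start)
  dt[]
}

# CpG site positions (+ strand cytosine, 1-based), >= 2 bp apart
place_cpgs <- function(cfg, truth) {
  sites <- list()
  # dense CpGs inside every planted span
  for (i in seq_len(nrow(truth))) {
    s <- truth$start[i]; e <- truth$end[i]
    gaps <- stats::rexp(ceiling((e - s) / cfg$dmr_cpg_spacing) * 2,
                        1 / cfg$dmr_cpg_spacing)
    pos <- s + 1L + as.integer(cumsum(pmax(gaps, 2)))
    pos <- pos[pos <= e - 1L]
    sites[[length(sites) + 1L]] <-
      data.table(chrom = truth$chrom[i], pos = pos)
  }
  planted <- rbindlist(c(list(data.table(chrom = character(),
                                         pos = integer())), sites))
  n_rest <- max(cfg$n_cpgs - nrow(planted), 0L)
  n_island <- round(n_rest * cfg$island_frac)
  n_unif <- n_rest - n_island
  probs <- cfg$genome / sum(cfg$genome)
  unif <- data.table(
    chrom = sample(names(cfg$genome), n_unif, TRUE, prob = probs))
  unif[, pos := sample.int(as.integer(cfg$genome[[chrom[1L]]]) - 2L,
                           .N, replace = TRUE) + 1L, by = chrom]
  # islands: Gamma-spaced runs of ~25 CpGs around random centers
  isl <- list()
  placed <- 0L
  while (placed < n_island) {
    ch <- sample(names(cfg$genome), 1L, prob = probs)
    k <- min(stats::rpois(1L, 25) + 5L, n_island - placed)
    center <- sample.int(cfg$genome[[ch]] - 10000L, 1L) + 5000L
    gaps <- pmax(stats::rgamma(k, shape = 2, scale = 25), 2)
    pos <- as.integer(center + cumsum(gaps))
    isl[[length(isl) + 1L]] <- data.table(chrom = ch, pos = pos)
    placed <- placed + k
  }
  all <- rbindlist(c(list(planted, unif), isl))
  all <- all[pos >= 2L & pos <= cfg$genome[chrom] - 1L]
  setorder(all, chrom, pos)
  # enforce >= 2 bp spacing so CpG dinucleotides do not overlap
  all <- all[, .SD[c(TRUE, diff(pos) >= 2L)], by = chrom]
  unique(all)
}

#' Simulate per-sample CpG methylomes with planted DMRs
#'
#' Per CpG site and sample, total read coverage ~ Poisson(coverage_mean)
#' (minimum 1) is split binomially between the two strands of the CpG
#' dinucleotide; methylated counts are Binomial(coverage, rate). Patient
#' samples of the targeted family have the site rate shifted by
#' sign * delta/100 inside planted spans (shared spans shift patients of
#' both families). Output calls are stranded (+ cytosine at p, - cytosine
#' at p+1) so destranding is exercised downstream.
#'
#' @param cfg a `sim_config`.
#' @param planted optional pre-built truth table (chrom, start, end,
#'   dmr_id, category, sign_, delta); defaults to fresh spans from `cfg`.
#' @param seed_offset added to `cfg$seed` (used to give iPSC runs their
#'   own noise stream).
#' @return list: `methylomes` (named list of `sample_methylome`),
#'   `truth` (planted DMR table), `sites` (CpG positions), `samples`
#'   (sheet).
#' @export
simulate_methylomes <- function(cfg, planted = NULL, seed_offset = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + seed_offset)
  truth <- if (is.null(planted)) plant_dmr_spans(cfg) else
    as.data.table(planted)
  sites <- place_cpgs(cfg, truth)
  n <- nrow(sites)

  # baseline rates: bimodal genome-wide, intermediate inside planted spans
  base <- stats::rbeta(n, cfg$baseline_beta[1L], cfg$baseline_beta[2L])
  site_tr <- sites_as_track(sites)
  sites[, dmr_id := NA_character_]
  sites[, sign_ := 0]
  sites[, category := NA_character_]
  if (nrow(truth)) {
    tt <- interval_track(truth[, .(chrom, start, end, name = dmr_id)],
                         track_name = "planted")
    # map member sites back through the planted track
    st <- as.data.table(site_tr)[, xid := .I]
    tk <- as.data.table(tt)
    setkey(tk, chrom, start, end)
    ov <- foverlaps(st, tk, by.x = c("chrom", "start", "end"),
                    type = "any", nomatch = NULL)
    ov <- ov[pmin(i.end, end) - pmax(i.start, start) > 0L]
    if (nrow(ov)) {
      sites$dmr_id[ov$xid] <- ov$name
      m <- match(sites$dmr_id, truth$dmr_id)
      sites[, sign_ := ifelse(is.na(m), 0, truth$sign_[m])]
      sites[, category := truth$category[m]]
    }
  }
  inside <- sites$sign_ != 0
  hyper <- inside & sites$sign_ > 0
  hypo <- inside & sites$sign_ < 0
  base[hyper] <- stats::runif(sum(hyper), 0.10, 1 - cfg$dmr_delta / 100 - 0.10)
  base[hypo] <- stats::runif(sum(hypo), cfg$dmr_delta / 100 + 0.10, 0.90)
  shifted_up <- base + cfg$dmr_delta / 100
  shifted_dn <- base - cfg$dmr_delta / 100
  if (any(hyper & (shifted_up > 1)) || any(hypo & (shifted_dn < 0)))
    stop("planted delta pushes methylation rate outside [0, 1]")

  samples <- sim_samples(cfg)
  # small per-family offsets at a random subset of sites
  off_sites <- stats::runif(n) < cfg$family_offset_frac
  offsets <- list()
  for (fam in names(cfg$families))
    offsets[[fam]] <- ifelse(off_sites,
                             stats::rnorm(n, 0, cfg$family_offset_sd), 0)

  methylomes <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    fam <- samples$family[si]
    status <- samples$status[si]
    rate <- base
    if (fam %in% names(offsets)) rate <- rate + offsets[[fam]]
    if (status == "patient") {
      target <- inside & (sites$category == "shared" |
                            (fam == "A" & sites$category == "familyA") |
                            (fam == "C" & sites$category == "familyC"))
      target[is.na(target)] <- FALSE
      rate[target] <- rate[target] + sites$sign_[target] *
        cfg$dmr_delta / 100
    }
    rate <- pmin(pmax(rate, 0.002), 0.998)
    cov <- pmax(stats::rpois(n, cfg$coverage_mean), 1L)
    cov_plus <- stats::rbinom(n, cov, 0.5)
    cov_minus <- cov - cov_plus
    meth_plus <- stats::rbinom(n, cov_plus, rate)
    meth_minus <- stats::rbinom(n, cov_minus, rate)
    plus <- data.table(chrom = sites$chrom, pos = sites$pos, strand = "+",
                       n_meth = meth_plus,
                       n_unmeth = cov_plus - meth_plus)[cov_plus > 0L]
    minus <- data.table(chrom = sites$chrom, pos = sites$pos + 1L,
                        strand = "-", n_meth = meth_minus,
                        n_unmeth = cov_minus - meth_minus)[cov_minus > 0L]
    calls <- rbindlist(list(plus, minus))
    methylomes[[si]] <- sample_methylome(
      calls, sample_id = samples$sample_id[si], family = fam,
      status = status)
  }
  names(methylomes) <- samples$sample_id
  list(methylomes = methylomes, truth = truth,
       sites = sites[, .(chrom, pos, dmr_id)], samples = samples)
}

#' Derive the persistent (iPSC) planted-DMR subset
#'
#' Retains `retain_frac` of the fibroblast planted DMRs; a fraction
#' `flip_frac` of the retained ones reverses sign (the hyper->hypo /
#' hypo->hyper classes).
#'
#' @param cfg a `sim_config`.
#' @param truth fibroblast planted DMR table.
#' @return planted table for the iPSC run (new dmr_ids, `source_dmr_id`
#'   kept).
#' @export
ipsc_truth_subset <- function(cfg, truth) {
  set.seed(cfg$seed + 7L)
  keep <- which(stats::runif(nrow(truth)) < cfg$ipsc$retain_frac)
  sub <- copy(truth[keep])
  flip <- stats::runif(nrow(sub)) < cfg$ipsc$flip_frac
  sub[, sign_ := ifelse(flip, -sign_, sign_)]
  sub[, `:=`(source_dmr_id = dmr_id,
             dmr_id = sprintf("ipsc_%s", dmr_id))]
  sub[]
}

#' Simulate companion annotation, LAD and DEG files
#'
#' Builds, consistently with the planted methylation structure:
#' * gene models tiled across the genome with random strands and exons;
#' * an "enhancer-state" track covering a fraction of planted DMRs (plus
#'   random background segments), an H3K4me1-like peak track, and a
#'   heterochromatin block track;
#' * control/DCM/fibroblast LAD tracks arranged so genes associated with
#'   planted DMRs mostly fall within 2 Mb of a GoL, and so the
#'   cross-cell-type conservation filter keeps most LoL/MoL and GoL;
#' * fibroblast (FDR column) and cardiac (p column) DEG tables whose
#'   log2 fold changes are signed opposite to the overlapping planted DMR
#'   with probability `rho`.
#'
#' @param cfg a `sim_config`.
#' @param truth planted DMR table from [simulate_methylomes()].
#' @return list: genes, tracks (list of `interval_track`), lads (list:
#'   dcm, control, fibroblast), degs (list: fibroblast, cardiac),
#'   deg_truth (gene_id, dmr_sign, is_deg).
#' @export
simulate_companions <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 13L)
  # --- gene models ----------------------------------------------------
  genes <- list()
  gid <- 0L
  for (ch in names(cfg$genome)) {
    pos <- 20000L
    while (pos < cfg$genome[[ch]] - 40000L) {
      gid <- gid + 1L
      len <- sample(5000:20000, 1L)
      strand <- sample(c("+", "-"), 1L)
      nex <- sample(3:8, 1L)
      bounds <- sort(sample(seq(pos, pos + len), 2L * nex))
      es <- bounds[seq(1L, 2L * nex, 2L)]
      ee <- bounds[seq(2L, 2L * nex, 2L)]
      ok <- ee > es
      genes[[gid]] <- data.table(
        gene_id = sprintf("g%04d", gid), chrom = ch, strand = strand,
        start = pos, end = pos + len,
        exon_starts = paste(es[ok], collapse = ","),
        exon_ends = paste(ee[ok], collapse = ","))
      pos <- pos + len + sample(25000:45000, 1L)
    }
  }
  genes <- rbindlist(genes)
  genes[, tss := fifelse(strand == "+", start, end)]
  setorder(genes, chrom, start)

  # --- chromatin tracks -----------------------------------------------
  rand_segments <- function(k, wmin, wmax, label) {
    probs <- cfg$genome / sum(cfg$genome)
    ch <- sample(names(cfg$genome), k, TRUE, prob = probs)
    w <- sample(wmin:wmax, k, TRUE)
    s <- vapply(seq_len(k), function(i)
      sample.int(cfg$genome[[ch[i]]] - w[i] - 1L, 1L), 0L)
    data.table(chrom = ch, start = s, end = s + w, name = label)
  }
  cover_dmrs <- function(frac, pad_lo, pad_hi, label) {
    idx <- which(stats::runif(nrow(truth)) < frac)
    if (!length(idx)) return(data.table())
    padl <- sample(pad_lo:pad_hi, length(idx), TRUE)
    padr <- sample(pad_lo:pad_hi, length(idx), TRUE)
    data.table(chrom = truth$chrom[idx],
               start = pmax(truth$start[idx] - padl, 0L),
               end = truth$end[idx] + padr, name = label)
  }
  enh <- rbindlist(list(cover_dmrs(0.6, 200L, 1000L, "enhancer"),
                        rand_segments(150L, 500L, 2000L, "enhancer")),
                   use.names = TRUE, fill = TRUE)
  h3k4me1 <- rbindlist(list(cover_dmrs(0.5, 500L, 2000L, "H3K4me1"),
                            rand_segments(250L, 1000L, 3000L, "H3K4me1")),
                       use.names = TRUE, fill = TRUE)
  het <- rand_segments(30L, 50000L, 200000L, "heterochromatin")
  tracks <- list(
    enhancer_state = interval_track(enh, track_name = "enhancer_state"),
    h3k4me1 = interval_track(h3k4me1, track_name = "H3K4me1"),
    heterochromatin = interval_track(het,
                                     track_name = "heterochromatin"))

  # --- DMR-gene linkage used for LADs and DEGs ------------------------
  gt <- interval_track(genes[, .(chrom,
                                 start = pmax(start - 50000L, 0L),
                                 end = end + 50000L, name = gene_id)],
                       track_name = "gene_windows")
  tt <- interval_track(truth[, .(chrom, start, end, name = dmr_id)],
                       track_name = "planted")
  st <- as.data.table(gt)[, xid := .I]
  tk <- as.data.table(tt); setkey(tk, chrom, start, end)
  ov <- foverlaps(st, tk, by.x = c("chrom", "start", "end"),
                  type = "any", nomatch = NULL)
  ov <- ov[pmin(i.end, end) - pmax(i.start, start) > 0L]
  assoc <- unique(ov[, .(gene_id = i.name, dmr_id = name)])
  assoc <- merge(assoc, truth[, .(dmr_id, sign_)], by = "dmr_id")
  gene_sign <- assoc[, .(dmr_sign = sign(sum(sign_))), by = gene_id]
  gene_sign <- gene_sign[dmr_sign != 0]

  # --- LAD tracks ------------------------------------------------------
  ctrl_blocks <- rand_segments(18L, 100000L, 400000L, "LAD")
  lose <- stats::runif(nrow(ctrl_blocks)) < 0.3          # future LoL
  dcm_keep <- ctrl_blocks[!lose]                          # MoL source
  # GoL blocks near a subset of planted DMRs (within ~2 Mb)
  gol_idx <- which(stats::runif(nrow(truth)) < 0.3)
  gol <- data.table()
  if (length(gol_idx)) {
    off <- sample(c(-1L, 1L), length(gol_idx), TRUE) *
      sample(200000:1500000, length(gol_idx), TRUE)
    w <- sample(50000:150000, length(gol_idx), TRUE)
    s <- pmax(truth$start[gol_idx] + off, 0L)
    e <- pmin(s + w, cfg$genome[truth$chrom[gol_idx]] - 1L)
    gol <- data.table(chrom = truth$chrom[gol_idx], start = s, end = e,
                      name = "LAD")[end > start]
  }
  dcm_blocks <- rbindlist(list(dcm_keep, gol), use.names = TRUE)
  # fibroblast LADs: most control blocks (keeps LoL/MoL after the
  # conservation filter) and none of the GoL additions
  fib_blocks <- ctrl_blocks[stats::runif(nrow(ctrl_blocks)) < 0.9]
  lads <- list(
    dcm = interval_merge(interval_track(dcm_blocks, track_name = "dcm"), 0L),
    control = interval_merge(interval_track(ctrl_blocks,
                                            track_name = "control"), 0L),
    fibroblast = interval_merge(interval_track(fib_blocks,
                                               track_name = "fibroblast"),
                                0L))
  # GoL additions overlapping a fibroblast LAD would be dropped by the
  # conservation filter; that is part of the stated world, not an error

  # --- DEG tables ------------------------------------------------------
  mk_degs <- function() {
    dt <- copy(genes[, .(gene_id)])
    dt <- merge(dt, gene_sign, by = "gene_id", all.x = TRUE)
    dt[, associated := !is.na(dmr_sign)]
    dt[, is_deg := fifelse(associated, stats::runif(.N) < 0.8,
                           stats::runif(.N) < 0.1)]
    inv <- stats::runif(nrow(dt)) < cfg$rho
    mag <- 0.5 + stats::rexp(nrow(dt), 1)
    dt[, log2_fc := fifelse(
      is_deg & associated,
      fifelse(inv, -dmr_sign, dmr_sign) * mag,
      fifelse(is_deg, sample(c(-1, 1), .N, TRUE) * mag,
              stats::rnorm(.N, 0, 0.3)))]
    dt[, p_value := fifelse(is_deg, 10^stats::runif(.N, -8, -3),
                            stats::runif(.N, 0.05, 1))]
    dt[, fdr := pmin(p_value * 5, 1)]
    dt[]
  }
  fib_degs <- mk_degs()
  # cardiac table: conserve most fibroblast DEGs, same sign
  cardiac <- copy(fib_degs)
  conserve <- stats::runif(nrow(cardiac)) < 0.7
  cardiac[, is_deg := is_deg & conserve]
  cardiac[, p_value := fifelse(is_deg, 10^stats::runif(.N, -8, -3),
                               stats::runif(.N, 0.05, 1))]
  cardiac[, fdr := pmin(p_value * 5, 1)]
  list(genes = genes, tracks = tracks, lads = lads,
       degs = list(
         fibroblast = fib_degs[, .(gene_id, log2_fc, p_value, fdr)],
         cardiac = cardiac[, .(gene_id, log2_fc, p_value, fdr)]),
       deg_truth = fib_degs[, .(gene_id, dmr_sign, is_deg)])
}

#' Write a complete synthetic fixture tree
#'
#' Runs [simulate_methylomes()] (fibroblast, and iPSC when enabled) and
#' [simulate_companions()] and writes everything as plain-text files:
#' sample sheets + coverage files, `genes.tsv`, `tracks/*.bed`,
#' `lads/*.bed`, `degs/*.tsv`, `truth/*.tsv`, `genome.chrom.sizes`.
#'
#' @param cfg a `sim_config`.
#' @param dir output directory (created).
#' @return invisibly, the list of generated objects.
#' @export
write_fixture_set <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("coverage_fibroblast", "coverage_ipsc", "tracks", "lads",
              "degs", "truth"))
    dir.create(file.path(dir, d), showWarnings = FALSE)
  fib <- simulate_methylomes(cfg)
  comp <- simulate_companions(cfg, fib$truth)
  write_cells <- function(sim, cell) {
    covdir <- file.path(dir, paste0("coverage_", cell))
    sheet <- copy(sim$samples)
    sheet[, path := file.path(paste0("coverage_", cell),
                              paste0(sample_id, ".cov"))]
    fwrite(sheet, file.path(dir, paste0("samples_", cell, ".tsv")),
           sep = "\t", quote = FALSE)
    for (m in sim$methylomes)
      write_methylation_calls(m, file.path(covdir,
                                           paste0(m$sample_id, ".cov")))
    fwrite(sim$truth, file.path(dir, "truth",
                                paste0("dmrs_", cell, ".tsv")),
           sep = "\t", quote = FALSE)
  }
  write_cells(fib, "fibroblast")
  ipsc <- NULL
  if (isTRUE(cfg$ipsc$enabled)) {
    itr <- ipsc_truth_subset(cfg, fib$truth)
    ipsc <- simulate_methylomes(cfg, planted = itr, seed_offset = 101L)
    write_cells(ipsc, "ipsc")
  }
  write_gene_models(comp$genes, file.path(dir, "genes.tsv"))
  for (nm in names(comp$tracks))
    write_bed(comp$tracks[[nm]], file.path(dir, "tracks",
                                           paste0(nm, ".bed")))
  for (nm in names(comp$lads))
    write_bed(comp$lads[[nm]], file.path(dir, "lads", paste0(nm, ".bed")))
  fwrite(comp$degs$fibroblast, file.path(dir, "degs", "fibroblast.tsv"),
         sep = "\t", quote = FALSE)
  fwrite(comp$degs$cardiac, file.path(dir, "degs", "cardiac.tsv"),
         sep = "\t", quote = FALSE)
  fwrite(comp$deg_truth, file.path(dir, "truth", "deg_truth.tsv"),
         sep = "\t", quote = FALSE)
  write_chrom_sizes(cfg$genome, file.path(dir, "genome.chrom.sizes"))
  invisible(list(fibroblast = fib, ipsc = ipsc, companions = comp))
}
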