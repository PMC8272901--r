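# A small shared synthetic world, built once per test run.

tiny_world_env <- new.env()

tiny_world <- function() {
  if (!is.null(tiny_world_env$w)) return(tiny_world_env$w)
  cfg <- sim_config(n_cpgs = 6000L,
                    n_dmrs = c(familyA = 15L, familyC = 15L, shared = 8L),
                    seed = 42L)
  sim <- simulate_methylomes(cfg)
  sheet <- sim$samples
  d_all <- group_design("all", sheet[status == "control", sample_id],
                        sheet[status == "patient", sample_id])
  d_A <- group_design("familyA",
                      sheet[family == "A" & status == "control", sample_id],
                      sheet[family == "A" & status == "patient", sample_id])
  d_C <- group_design("familyC",
                      sheet[family == "C" & status == "control", sample_id],
                      sheet[family == "C" & status == "patient", sample_id])
  um_all <- unite_methylomes(sim$methylomes[c(d_all$control_ids,
                                              d_all$patient_ids)])
  um_A <- unite_methylomes(sim$methylomes[c(d_A$control_ids,
                                            d_A$patient_ids)])
  um_C <- unite_methylomes(sim$methylomes[c(d_C$control_ids,
                                            d_C$patient_ids)])
  dm_all <- call_dmcpgs(um_all, d_all)
  dm_A <- call_dmcpgs(um_A, d_A)
  dm_C <- call_dmcpgs(um_C, d_C)
  w <- list(cfg = cfg, sim = sim, designs = list(all = d_all, A = d_A,
                                                 C = d_C),
            um = list(all = um_all, A = um_A, C = um_C),
            dm = list(all = dm_all, A = dm_A, C = dm_C),
            tiles = list(all = tile_dmrs(dm_all)$tiles,
                         A = tile_dmrs(dm_A)$tiles,
                         C = tile_dmrs(dm_C)$tiles))
  tiny_world_env$w <- w
  w
}

# reciprocal-overlap matching of tiles against a truth table
match_tiles_to_truth <- function(tiles, truth, frac = 0.5) {
  t <- as.data.table(tiles)[, .(chrom, start, end)]
  m <- merge(t, as.data.table(truth), by = "chrom",
             allow.cartesian = TRUE, suffixes = c("", ".t"))
  m[, ovl := pmin(end, end.t) - pmax(start, start.t)]
  m[ovl > 0 & ovl >= frac * (end - start) &
      ovl >= frac * (end.t - start.t)]
}
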