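utils::globalVariables(c("stage", "value", "metric"))

# classed errors so the CLI can map them to distinct exit codes
ep_config_error <- function(...)
  stop(structure(class = c("epihotspot_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
ep_dependency_error <- function(...)
  stop(structure(class = c("epihotspot_dependency_error", "error",
                           "condition"),
                 list(message = paste0(...), call = NULL)))
ep_data_error <- function(...)
  stop(structure(class = c("epihotspot_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))

#' Default pipeline configuration
#'
#' All thresholds default to the analysis' stated values: minimum coverage
#' 5x, DMCpG q <= 0.01 and |difference| >= 30 percent points, tile merge
#' gap 500 bp and minimum tile size 100 bp, fibroblast DEG FDR <= 0.05,
#' cardiac DEG p <= 0.05, LAD distance window 2 Mb, regulatory-domain
#' parameters 5 kb upstream / 1 kb downstream / 1 Mb distal.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param overrides nested list merged over the defaults (e.g. from YAML).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "epihotspot_out", seed = 1L,
                            overrides = list()) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    thresholds = list(min_cov = 5L, diff_cutoff = 30, q_cutoff = 0.01,
                      merge_gap = 500L, min_tile = 100L, deg_fdr = 0.05,
                      cardiac_p = 0.05, lad_window = 2e6),
    great = list(proximal_up = 5000L, proximal_down = 1000L,
                 distal_max = 1000000L),
    min_overlap_bp = 1L,
    sim = list(),
    verbose = TRUE)
  cfg <- modifyList(cfg, overrides)
  bad <- vapply(cfg$thresholds, function(x) !is.numeric(x) || x <= 0,
                TRUE)
  if (any(bad))
    ep_config_error("non-positive threshold(s): ",
                    paste(names(cfg$thresholds)[bad], collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override the defaults of [pipeline_config()]; the `sim`
#' block overrides [sim_config()] defaults.
#'
#' @param path YAML file.
#' @param out_dir,seed optional overrides of the file's values.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  if (!file.exists(path)) ep_config_error("no such config file: ", path)
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) ep_config_error("bad YAML: ",
                                                    conditionMessage(e)))
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(seed)) y$seed <- seed
  pipeline_config(out_dir = y$out_dir %||% "epihotspot_out",
                  seed = y$seed %||% 1L,
                  overrides = y[setdiff(names(y), c("out_dir", "seed"))])
}

stage_order <- c("simulate", "unite", "dmcpg", "tile", "classify",
                 "annotate", "enrich", "concordance", "lads", "hotspots",
                 "persistence", "report")

stage_deps <- list(
  simulate = character(),
  unite = "simulate",
  dmcpg = "unite",
  tile = "dmcpg",
  classify = c("tile", "unite"),
  annotate = c("classify", "simulate"),
  enrich = c("classify", "unite", "simulate"),
  concordance = c("annotate", "classify", "simulate"),
  lads = c("annotate", "simulate"),
  hotspots = c("dmcpg", "unite"),
  persistence = c("tile", "unite"),
  report = c("classify", "enrich", "concordance", "lads", "hotspots",
             "persistence"))

p_out <- function(cfg, ...) file.path(cfg$out_dir, ...)

manifest_path <- function(cfg, stage) p_out(cfg, "manifests",
                                            paste0(stage, ".json"))

# hashes keyed by path relative to out_dir, so manifests do not embed
# absolute paths and identical runs are byte-identical
rel_out <- function(cfg, paths) {
  base <- paste0(normalizePath(cfg$out_dir, mustWork = FALSE), "/")
  sub(base, "", normalizePath(paths, mustWork = FALSE), fixed = TRUE)
}

hash_files <- function(cfg, paths) {
  paths <- sort(unique(paths[file.exists(paths)]))
  h <- as.vector(tools::md5sum(paths))
  stats::setNames(h, rel_out(cfg, paths))
}

stage_log <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message("[epihotspot] ", ...)
}

write_manifest <- function(cfg, stage, inputs, outputs, params) {
  dir.create(p_out(cfg, "manifests"), recursive = TRUE,
             showWarnings = FALSE)
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion(
                "epihotspot")),
              seed = cfg$seed,
              params = params,
              input_hashes = as.list(hash_files(cfg, inputs)),
              output_hashes = as.list(hash_files(cfg, outputs)))
  jsonlite::write_json(man, manifest_path(cfg, stage), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(man)
}

# TRUE when the stage's recorded inputs still hash identically and all of
# its recorded outputs exist
stage_current <- function(cfg, stage) {
  mp <- manifest_path(cfg, stage)
  if (!file.exists(mp)) return(FALSE)
  man <- jsonlite::read_json(mp)
  ins <- file.path(cfg$out_dir, names(man$input_hashes))
  outs <- file.path(cfg$out_dir, names(man$output_hashes))
  if (!all(file.exists(c(ins, outs)))) return(FALSE)
  if (!length(ins)) return(TRUE)
  new <- as.vector(tools::md5sum(ins))
  all(new == unlist(man$input_hashes))
}

check_deps <- function(cfg, stage) {
  for (d in stage_deps[[stage]])
    if (!file.exists(manifest_path(cfg, d)))
      ep_dependency_error("stage '", stage, "' requires stage '", d,
                          "' to have run first")
}

# ---- stage implementations -------------------------------------------------

st_simulate <- function(cfg) {
  scfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  write_fixture_set(scfg, p_out(cfg, "fixture"))
  list(inputs = character(),
       outputs = c(p_out(cfg, "fixture", "samples_fibroblast.tsv"),
                   p_out(cfg, "fixture", "genes.tsv"),
                   p_out(cfg, "fixture", "genome.chrom.sizes")),
       params = cfg$sim)
}

pipeline_designs <- function(sheet) {
  list(
    all = group_design("all", sheet[status == "control", sample_id],
                       sheet[status == "patient", sample_id]),
    familyA = group_design(
      "familyA", sheet[family == "A" & status == "control", sample_id],
      sheet[family == "A" & status == "patient", sample_id]),
    familyC = group_design(
      "familyC", sheet[family == "C" & status == "control", sample_id],
      sheet[family == "C" & status == "patient", sample_id]))
}

pipeline_cell_types <- function(cfg) {
  cells <- "fibroblast"
  if (file.exists(p_out(cfg, "fixture", "samples_ipsc.tsv")))
    cells <- c(cells, "ipsc")
  cells
}

st_unite <- function(cfg) {
  dir.create(p_out(cfg, "united"), showWarnings = FALSE, recursive = TRUE)
  ins <- character(); outs <- character()
  for (cell in pipeline_cell_types(cfg)) {
    sheet_path <- p_out(cfg, "fixture", paste0("samples_", cell, ".tsv"))
    sheet <- read_sample_sheet(sheet_path)
    ms <- load_samples(sheet)
    ins <- c(ins, sheet_path, sheet$path)
    designs <- pipeline_designs(sheet)
    for (run in names(designs)) {
      d <- designs[[run]]
      um <- unite_methylomes(ms[c(d$control_ids, d$patient_ids)],
                             min_cov = cfg$thresholds$min_cov)
      out <- p_out(cfg, "united", paste0(cell, "_", run, ".tsv"))
      write_united(um, out)
      outs <- c(outs, out)
    }
  }
  list(inputs = ins, outputs = outs,
       params = list(min_cov = cfg$thresholds$min_cov))
}

st_dmcpg <- function(cfg) {
  dir.create(p_out(cfg, "dmcpg"), showWarnings = FALSE, recursive = TRUE)
  ins <- character(); outs <- character()
  for (cell in pipeline_cell_types(cfg)) {
    sheet <- read_sample_sheet(p_out(cfg, "fixture",
                                     paste0("samples_", cell, ".tsv")))
    designs <- pipeline_designs(sheet)
    for (run in names(designs)) {
      up <- p_out(cfg, "united", paste0(cell, "_", run, ".tsv"))
      if (!file.exists(up)) ep_dependency_error("missing ", up)
      um <- read_united(up)
      dm <- call_dmcpgs(um, designs[[run]],
                        diff_cutoff = cfg$thresholds$diff_cutoff,
                        q_cutoff = cfg$thresholds$q_cutoff)
      out <- p_out(cfg, "dmcpg", paste0(cell, "_", run, ".tsv"))
      write_dmcpgs(dm, out)
      ins <- c(ins, up); outs <- c(outs, out)
    }
  }
  list(inputs = ins, outputs = outs,
       params = cfg$thresholds[c("diff_cutoff", "q_cutoff")])
}

st_tile <- function(cfg) {
  dir.create(p_out(cfg, "tiles"), showWarnings = FALSE, recursive = TRUE)
  ins <- character(); outs <- character()
  for (cell in pipeline_cell_types(cfg)) {
    for (run in c("all", "familyA", "familyC")) {
      dp <- p_out(cfg, "dmcpg", paste0(cell, "_", run, ".tsv"))
      if (!file.exists(dp)) ep_dependency_error("missing ", dp)
      dm <- read_dmcpgs(dp)
      tl <- tile_dmrs(dm, merge_gap = cfg$thresholds$merge_gap,
                      min_size = cfg$thresholds$min_tile)
      out <- p_out(cfg, "tiles", paste0(cell, "_", run, ".tsv"))
      write_tiles(tl$tiles, out)
      ins <- c(ins, dp); outs <- c(outs, out)
    }
  }
  list(inputs = ins, outputs = outs,
       params = cfg$thresholds[c("merge_gap", "min_tile")])
}

st_classify <- function(cfg) {
  dir.create(p_out(cfg, "classify"), showWarnings = FALSE,
             recursive = TRUE)
  ins <- character(); outs <- character()
  for (cell in pipeline_cell_types(cfg)) {
    tp <- function(run) p_out(cfg, "tiles", paste0(cell, "_", run, ".tsv"))
    up <- function(run) p_out(cfg, "united",
                              paste0(cell, "_", run, ".tsv"))
    for (f in c(tp("all"), tp("familyA"), tp("familyC"),
                up("familyA"), up("familyC")))
      if (!file.exists(f)) ep_dependency_error("missing ", f)
    cls <- classify_tiles(read_tiles(tp("all")), read_tiles(tp("familyA")),
                          read_tiles(tp("familyC")),
                          read_united(up("familyA")),
                          read_united(up("familyC")),
                          min_overlap_bp = cfg$min_overlap_bp,
                          cell_type = cell)
    out <- p_out(cfg, "classify", paste0(cell, "_classified.tsv"))
    write_tiles(cls, out)
    ins <- c(ins, tp("all"), tp("familyA"), tp("familyC"),
             up("familyA"), up("familyC"))
    outs <- c(outs, out)
  }
  list(inputs = ins, outputs = outs,
       params = list(min_overlap_bp = cfg$min_overlap_bp))
}

st_annotate <- function(cfg) {
  dir.create(p_out(cfg, "annotate"), showWarnings = FALSE,
             recursive = TRUE)
  gp <- p_out(cfg, "fixture", "genes.tsv")
  if (!file.exists(gp)) ep_dependency_error("missing ", gp)
  genes <- read_gene_models(gp)
  feats <- gene_feature_tracks(genes)
  ins <- gp; outs <- character()
  for (cell in pipeline_cell_types(cfg)) {
    up <- p_out(cfg, "united", paste0(cell, "_all.tsv"))
    um <- read_united(up)
    lab <- assign_feature(um$sites, feats)
    fr <- as.data.table(table(feature = lab))
    out <- p_out(cfg, "annotate",
                 paste0("feature_fractions_", cell, ".tsv"))
    fwrite(fr[, .(feature, n = N, fraction = N / sum(N))], out,
           sep = "\t", quote = FALSE)
    cp <- p_out(cfg, "classify", paste0(cell, "_classified.tsv"))
    tiles <- read_tiles(cp)
    tiles[, tile_id := .I]
    assoc <- great_associate(tiles, genes,
                             proximal_up = cfg$great$proximal_up,
                             proximal_down = cfg$great$proximal_down,
                             distal_max = cfg$great$distal_max)
    out2 <- p_out(cfg, "annotate", paste0("great_assoc_", cell, ".tsv"))
    fwrite(assoc, out2, sep = "\t", quote = FALSE)
    ins <- c(ins, up, cp); outs <- c(outs, out, out2)
  }
  list(inputs = ins, outputs = outs, params = cfg$great)
}

st_enrich <- function(cfg) {
  dir.create(p_out(cfg, "enrich"), showWarnings = FALSE, recursive = TRUE)
  genes <- read_gene_models(p_out(cfg, "fixture", "genes.tsv"))
  track_files <- list.files(p_out(cfg, "fixture", "tracks"),
                            full.names = TRUE, pattern = "\\.bed$")
  ins <- c(p_out(cfg, "fixture", "genes.tsv"), track_files)
  outs <- character()
  for (cell in pipeline_cell_types(cfg)) {
    up <- p_out(cfg, "united", paste0(cell, "_all.tsv"))
    cp <- p_out(cfg, "classify", paste0(cell, "_classified.tsv"))
    um <- read_united(up)
    tiles <- read_tiles(cp)
    bg <- um$sites
    rows <- list()
    tss_rows <- list()
    for (cat in unique(tiles$category)) {
      tt <- tiles_as_track(tiles[category == cat],
                           track_name = cat)
      dm <- bg[tiles_found_in(sites_as_track(bg), tt)]
      if (!nrow(dm)) next
      for (tf in track_files) {
        ctx <- read_bed(tf)
        r <- odds_ratio(dm, bg, ctx)
        r[, `:=`(category = cat)]
        rows[[length(rows) + 1L]] <- r
      }
      tb <- tss_distance_bins(dm, bg, genes)
      tb[, category := cat]
      tss_rows[[length(tss_rows) + 1L]] <- tb
    }
    out1 <- p_out(cfg, "enrich", paste0("or_tracks_", cell, ".tsv"))
    out2 <- p_out(cfg, "enrich", paste0("or_tss_bins_", cell, ".tsv"))
    fwrite(rbindlist(rows), out1, sep = "\t", quote = FALSE)
    fwrite(rbindlist(tss_rows), out2, sep = "\t", quote = FALSE)
    ins <- c(ins, up, cp); outs <- c(outs, out1, out2)
  }
  list(inputs = ins, outputs = outs, params = list())
}

st_concordance <- function(cfg) {
  dir.create(p_out(cfg, "concordance"), showWarnings = FALSE,
             recursive = TRUE)
  dp <- p_out(cfg, "fixture", "degs", "fibroblast.tsv")
  ap <- p_out(cfg, "annotate", "great_assoc_fibroblast.tsv")
  cp <- p_out(cfg, "classify", "fibroblast_classified.tsv")
  for (f in c(dp, ap, cp))
    if (!file.exists(f)) ep_dependency_error("missing ", f)
  degs <- filter_degs(read_degs(dp), fdr_max = cfg$thresholds$deg_fdr)
  assoc <- fread(ap)
  tiles <- read_tiles(cp); tiles[, tile_id := .I]
  dc <- direction_concordance(tiles, assoc, degs)
  out1 <- p_out(cfg, "concordance", "pairs.tsv")
  fwrite(dc$pairs, out1, sep = "\t", quote = FALSE)
  sm <- data.table(metric = c(names(dc$fractions), "qcr",
                              "fraction_inverse", "n_pairs"),
                   value = c(dc$fractions, dc$qcr$qcr,
                             dc$fraction_inverse, dc$qcr$n_total))
  out2 <- p_out(cfg, "concordance", "summary.tsv")
  fwrite(sm, out2, sep = "\t", quote = FALSE)
  list(inputs = c(dp, ap, cp), outputs = c(out1, out2),
       params = list(deg_fdr = cfg$thresholds$deg_fdr))
}

st_lads <- function(cfg) {
  dir.create(p_out(cfg, "lads"), showWarnings = FALSE, recursive = TRUE)
  lp <- function(x) p_out(cfg, "fixture", "lads", paste0(x, ".bed"))
  gp <- p_out(cfg, "fixture", "genes.tsv")
  fd <- p_out(cfg, "fixture", "degs", "fibroblast.tsv")
  cd <- p_out(cfg, "fixture", "degs", "cardiac.tsv")
  ap <- p_out(cfg, "annotate", "great_assoc_fibroblast.tsv")
  for (f in c(lp("dcm"), lp("control"), lp("fibroblast"), gp, fd, cd, ap))
    if (!file.exists(f)) ep_dependency_error("missing ", f)
  redist <- lad_redistribute(read_bed(lp("dcm")), read_bed(lp("control")))
  cons <- conserve_across_celltypes(redist, read_bed(lp("fibroblast")))
  for (nm in c("gol", "lol", "mol")) {
    write_bed(redist[[nm]], p_out(cfg, "lads", paste0(nm, ".bed")))
    write_bed(cons[[nm]], p_out(cfg, "lads",
                                paste0("conserved_", nm, ".bed")))
  }
  genes <- read_gene_models(gp)
  fib <- filter_degs(read_degs(fd), fdr_max = cfg$thresholds$deg_fdr)
  card <- filter_degs(read_degs(cd), p_max = cfg$thresholds$cardiac_p)
  conserved <- filter_and_intersect_degs(fib, card)
  assoc <- fread(ap)
  dmr_assoc_genes <- intersect(conserved, unique(assoc$gene_id))
  focal <- genes[gene_id %in% dmr_assoc_genes]
  if (!nrow(focal)) ep_data_error("no conserved DMR-associated DEGs")
  dl <- deg_lad_distance(focal, cons, window = cfg$thresholds$lad_window,
                         background_genes = genes)
  out1 <- p_out(cfg, "lads", "deg_lad.tsv")
  fwrite(dl$per_gene, out1, sep = "\t", quote = FALSE)
  out2 <- p_out(cfg, "lads", "deg_lad_or.tsv")
  fwrite(dl$or, out2, sep = "\t", quote = FALSE)
  list(inputs = c(lp("dcm"), lp("control"), lp("fibroblast"), gp, fd, cd,
                  ap),
       outputs = c(out1, out2,
                   p_out(cfg, "lads", c("gol.bed", "lol.bed", "mol.bed"))),
       params = cfg$thresholds[c("deg_fdr", "cardiac_p", "lad_window")])
}

st_hotspots <- function(cfg) {
  dir.create(p_out(cfg, "hotspots"), showWarnings = FALSE,
             recursive = TRUE)
  dmf <- function(cell, run) p_out(cfg, "dmcpg",
                                   paste0(cell, "_", run, ".tsv"))
  unf <- function(cell, run) p_out(cfg, "united",
                                   paste0(cell, "_", run, ".tsv"))
  ins <- character(); outs <- character()
  # inter-family proximity in fibroblasts (density mode, Wilcoxon)
  dmA <- read_dmcpgs(dmf("fibroblast", "familyA"))
  dmC <- read_dmcpgs(dmf("fibroblast", "familyC"))
  bgA <- read_united(unf("fibroblast", "familyA"))$sites
  bgC <- read_united(unf("fibroblast", "familyC"))$sites
  if (nrow(dmA) && nrow(dmC)) {
    pr <- hotspot_proximity(dmA, dmC, bgC, mode = "density",
                            seed = cfg$seed, query_background = bgA)
    write_proximity_result(pr, p_out(cfg, "hotspots", "interfamily.tsv"),
                           p_out(cfg, "hotspots", "interfamily.json"))
    outs <- c(outs, p_out(cfg, "hotspots",
                          c("interfamily.tsv", "interfamily.json")))
  }
  ins <- c(ins, dmf("fibroblast", "familyA"), dmf("fibroblast", "familyC"),
           unf("fibroblast", "familyA"), unf("fibroblast", "familyC"))
  # inter-cell-type proximity (binned mode, one-tailed Fisher)
  if ("ipsc" %in% pipeline_cell_types(cfg)) {
    for (run in c("familyA", "familyC")) {
      dmI <- read_dmcpgs(dmf("ipsc", run))
      dmFb <- read_dmcpgs(dmf("fibroblast", run))
      bgF <- read_united(unf("fibroblast", run))$sites
      bgI <- read_united(unf("ipsc", run))$sites
      ins <- c(ins, dmf("ipsc", run), dmf("fibroblast", run),
               unf("fibroblast", run), unf("ipsc", run))
      if (!nrow(dmI) || !nrow(dmFb)) next
      pr <- hotspot_proximity(dmI, dmFb, bgF, mode = "binned",
                              seed = cfg$seed, query_background = bgI)
      base <- paste0("intercelltype_", run)
      write_proximity_result(pr,
                             p_out(cfg, "hotspots", paste0(base, ".tsv")),
                             p_out(cfg, "hotspots", paste0(base, ".json")))
      outs <- c(outs, p_out(cfg, "hotspots",
                            paste0(base, c(".tsv", ".json"))))
    }
  }
  list(inputs = ins, outputs = outs, params = list(seed = cfg$seed))
}

st_persistence <- function(cfg) {
  dir.create(p_out(cfg, "persistence"), showWarnings = FALSE,
             recursive = TRUE)
  if (!"ipsc" %in% pipeline_cell_types(cfg))
    ep_dependency_error("persistence needs an iPSC sample set")
  fib <- rbindlist(lapply(c("all", "familyA", "familyC"), function(r)
    read_tiles(p_out(cfg, "tiles", paste0("fibroblast_", r, ".tsv")))),
    use.names = TRUE)
  ip <- rbindlist(lapply(c("all", "familyA", "familyC"), function(r)
    read_tiles(p_out(cfg, "tiles", paste0("ipsc_", r, ".tsv")))),
    use.names = TRUE)
  pers <- classify_persistence(fib, ip,
                               read_united(p_out(cfg, "united",
                                                 "fibroblast_all.tsv")),
                               read_united(p_out(cfg, "united",
                                                 "ipsc_all.tsv")))
  out <- p_out(cfg, "persistence", "persistence.tsv")
  fwrite(pers, out, sep = "\t", quote = FALSE)
  list(inputs = c(p_out(cfg, "tiles",
                        paste0(rep(c("fibroblast_", "ipsc_"), each = 3L),
                               c("all", "familyA", "familyC"), ".tsv")),
                  p_out(cfg, "united", c("fibroblast_all.tsv",
                                         "ipsc_all.tsv"))),
       outputs = out, params = list())
}

st_report <- function(cfg) {
  rows <- list()
  for (cell in pipeline_cell_types(cfg)) {
    cp <- p_out(cfg, "classify", paste0(cell, "_classified.tsv"))
    if (file.exists(cp)) {
      t <- read_tiles(cp)
      tab <- t[, .N, by = .(category, direction)]
      for (i in seq_len(nrow(tab)))
        rows[[length(rows) + 1L]] <- data.table(
          stage = "classify", cell = cell,
          metric = paste0("n_", tab$category[i], "_", tab$direction[i]),
          value = tab$N[i])
    }
  }
  sm <- p_out(cfg, "concordance", "summary.tsv")
  if (file.exists(sm)) {
    s <- fread(sm)
    for (i in seq_len(nrow(s)))
      rows[[length(rows) + 1L]] <- data.table(
        stage = "concordance", cell = "fibroblast",
        metric = s$metric[i], value = as.numeric(s$value[i]))
  }
  dir.create(p_out(cfg, "report"), showWarnings = FALSE, recursive = TRUE)
  out <- p_out(cfg, "report", "summary.tsv")
  fwrite(rbindlist(rows), out, sep = "\t", quote = FALSE)
  list(inputs = c(sm), outputs = out, params = list())
}

stage_fns <- list(simulate = st_simulate, unite = st_unite,
                  dmcpg = st_dmcpg, tile = st_tile, classify = st_classify,
                  annotate = st_annotate, enrich = st_enrich,
                  concordance = st_concordance, lads = st_lads,
                  hotspots = st_hotspots, persistence = st_persistence,
                  report = st_report)

#' Run one pipeline stage
#'
#' Checks the stage's declared dependencies (their manifests must exist),
#' runs it, and writes a JSON manifest (parameters, seed, input/output
#' md5 hashes, package version; no timestamps, so identical runs produce
#' byte-identical manifests). Re-running a stage whose recorded input
#' hashes are unchanged is a no-op unless `force`.
#'
#' @param name stage name, one of simulate, unite, dmcpg, tile, classify,
#'   annotate, enrich, concordance, lads, hotspots, persistence, report.
#' @param cfg a `pipeline_config`.
#' @param force re-run even when inputs are unchanged.
#' @return invisibly, the stage manifest (list); attribute `skipped` TRUE
#'   when the stage was a no-op.
#' @export
run_stage <- function(name, cfg, force = FALSE) {
  if (!name %in% stage_order)
    ep_config_error("unknown stage: ", name)
  if (!inherits(cfg, "pipeline_config"))
    ep_config_error("cfg is not a pipeline_config")
  check_deps(cfg, name)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  if (!force && stage_current(cfg, name)) {
    stage_log(cfg, "stage ", name, ": inputs unchanged, skipping")
    man <- jsonlite::read_json(manifest_path(cfg, name))
    attr(man, "skipped") <- TRUE
    return(invisible(man))
  }
  res <- stage_fns[[name]](cfg)
  man <- write_manifest(cfg, name, res$inputs, res$outputs, res$params)
  stage_log(cfg, sprintf("stage %-12s done in %.1fs (%d outputs)", name,
                         proc.time()[["elapsed"]] - t0,
                         length(res$outputs)))
  invisible(man)
}

#' Run the whole pipeline (or a prefix of stages)
#'
#' @param cfg a `pipeline_config`.
#' @param stages stage names in order (default: all that can run).
#' @param force passed to [run_stage()].
#' @return invisibly, list of manifests.
#' @export
run_pipeline <- function(cfg, stages = stage_order, force = FALSE) {
  stages <- stage_order[stage_order %in% stages]
  mans <- list()
  for (s in stages) mans[[s]] <- run_stage(s, cfg, force = force)
  invisible(mans)
}
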