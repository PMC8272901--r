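utils::globalVariables(c(
  "meth_diff", "p_value", "q_value", "n_dmcpgs", "mean_diff", "direction",
  "tile_id", "run", "category", "in_all", "in_A", "in_C", "eligible",
  "fib_state", "ipsc_state", "persistence", "cell_type", "sign_", "q"
))

#' Define a two-group comparison
#'
#' @param label run label, e.g. "all", "familyA", "familyC".
#' @param control_ids,patient_ids disjoint, non-empty sample-id vectors.
#' @return a `group_design` object.
#' @export
group_design <- function(label, control_ids, patient_ids) {
  if (!length(control_ids) || !length(patient_ids))
    stop("both groups must be non-empty")
  if (length(intersect(control_ids, patient_ids)))
    stop("control and patient groups overlap")
  structure(list(label = label,
                 control_ids = as.character(control_ids),
                 patient_ids = as.character(patient_ids)),
            class = "group_design")
}

# vectorized binomial log-likelihood sum(m log p + (t-m) log(1-p)), with
# the 0*log(0) = 0 convention
binom_ll <- function(m, t, p) {
  l1 <- ifelse(m > 0, m * log(p), 0)
  l2 <- ifelse(t - m > 0, (t - m) * log1p(-p), 0)
  l1 + l2
}

#' Call differentially methylated CpGs
#'
#' Per position, patient and control methylated/unmethylated counts are
#' compared with a binomial likelihood-ratio test -- the closed form of the
#' logistic regression of methylation on group (chi-square, 1 df), i.e.
#' methylKit's replicate-aware default. For 1-vs-1 designs a Fisher exact
#' test on pooled counts is available. P-values are Benjamini-Hochberg
#' corrected over all tested positions; records must satisfy both
#' `q <= q_cutoff` and `|meth_diff| >= diff_cutoff` to be retained.
#'
#' `meth_diff` is mean(patient per-sample percent) - mean(control
#' per-sample percent): negative = patient hypomethylated, positive =
#' patient hypermethylated.
#'
#' @param um a `united_matrix` containing all design samples.
#' @param design a `group_design`.
#' @param diff_cutoff minimum |methylation difference| in percent points
#'   (default 30).
#' @param q_cutoff maximum BH-adjusted q-value (default 0.01).
#' @param test "lrt" (default) or "fisher" (pooled counts).
#' @return data.table of retained DMCpGs (chrom, pos, meth_diff, p_value,
#'   q_value), with attributes `n_tested`, `test`, `correction`, `design`.
#' @export
call_dmcpgs <- function(um, design, diff_cutoff = 30, q_cutoff = 0.01,
                        test = c("lrt", "fisher")) {
  test <- match.arg(test)
  stopifnot(inherits(um, "united_matrix"), inherits(design, "group_design"))
  ids <- colnames(um$meth)
  miss <- setdiff(c(design$control_ids, design$patient_ids), ids)
  if (length(miss))
    stop("design samples absent from matrix: ", paste(miss, collapse = ", "))
  ci <- match(design$control_ids, ids)
  pi_ <- match(design$patient_ids, ids)

  mC <- um$meth[, ci, drop = FALSE]; tC <- um$cov[, ci, drop = FALSE]
  mP <- um$meth[, pi_, drop = FALSE]; tP <- um$cov[, pi_, drop = FALSE]
  MC <- rowSums(mC); TC <- rowSums(tC)
  MP <- rowSums(mP); TP <- rowSums(tP)

  if (test == "lrt") {
    p0 <- (MC + MP) / (TC + TP)
    pC <- MC / TC
    pP <- MP / TP
    lrt <- 2 * (binom_ll(MC, TC, pC) + binom_ll(MP, TP, pP) -
                  binom_ll(MC + MP, TC + TP, p0))
    lrt <- pmax(lrt, 0)
    p <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  } else {
    p <- vapply(seq_along(MC), function(i)
      stats::fisher.test(matrix(c(MP[i], TP[i] - MP[i],
                                  MC[i], TC[i] - MC[i]), 2L))$p.value,
      0)
  }
  q <- stats::p.adjust(p, method = "BH")
  diff <- rowMeans(100 * mP / tP) - rowMeans(100 * mC / tC)

  keep <- q <= q_cutoff & abs(diff) >= diff_cutoff
  out <- data.table(chrom = um$sites$chrom[keep], pos = um$sites$pos[keep],
                    meth_diff = diff[keep], p_value = p[keep],
                    q_value = q[keep])
  setorder(out, chrom, pos)
  setattr(out, "n_tested", length(p))
  setattr(out, "test", test)
  setattr(out, "correction", "BH")
  setattr(out, "design", design$label)
  out[]
}

#' Write / read a DMCpG table
#'
#' TSV with header chrom, pos, meth_diff, p_value, q_value; `#`-prefixed
#' comment lines carry run provenance.
#'
#' @param dmcpgs data.table from [call_dmcpgs()].
#' @param path file path.
#' @return invisibly `path` (writer); the data.table (reader).
#' @export
write_dmcpgs <- function(dmcpgs, path) {
  hdr <- sprintf("# design=%s test=%s correction=%s n_tested=%s",
                 attr(dmcpgs, "design") %||% NA,
                 attr(dmcpgs, "test") %||% NA,
                 attr(dmcpgs, "correction") %||% NA,
                 attr(dmcpgs, "n_tested") %||% NA)
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  fwrite(dmcpgs, path, sep = "\t", append = TRUE, col.names = TRUE,
         quote = FALSE)
  invisible(path)
}

#' @rdname write_dmcpgs
#' @export
read_dmcpgs <- function(path) {
  dt <- fread(path, sep = "\t", skip = "chrom\tpos")
  setorder(dt, chrom, pos)
  dt[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build DMR tiles from DMCpGs
#'
#' (i) DMCpGs within `merge_gap` bp of one another on the same chromosome
#' are merged (single linkage) into one tile spanning the first to the last
#' member site; (ii) tiles whose members disagree in sign are ambiguous and
#' removed (counted); (iii) tiles shorter than `min_size` bp are extended
#' symmetrically to exactly `min_size` -- both sides grow by
#' `ceiling(deficit/2)` and one bp is trimmed from the right if the parity
#' overshoots, clipping at coordinate 0 with the remainder pushed right;
#' (iv) `mean_diff` is the arithmetic mean of member differences.
#'
#' Tiles are 0-based half-open; a tile over member positions p1..pk spans
#' `[p1-1, pk)` before extension.
#'
#' @param dmcpgs data.table with chrom, pos, meth_diff.
#' @param merge_gap maximum distance between neighboring member CpGs
#'   (default 500 bp).
#' @param min_size minimum tile width (default 100 bp).
#' @return list with `tiles` (data.table: chrom, start, end, n_dmcpgs,
#'   mean_diff, direction) and `n_ambiguous_removed`.
#' @export
tile_dmrs <- function(dmcpgs, merge_gap = 500L, min_size = 100L) {
  dt <- as.data.table(dmcpgs)[, .(chrom = as.character(chrom),
                                  pos = as.integer(pos),
                                  meth_diff = as.numeric(meth_diff))]
  if (!nrow(dt))
    return(list(tiles = data.table(chrom = character(), start = integer(),
                                   end = integer(), n_dmcpgs = integer(),
                                   mean_diff = numeric(),
                                   direction = character()),
                n_ambiguous_removed = 0L))
  setorder(dt, chrom, pos)
  dt[, newgrp := c(TRUE, diff(pos) > merge_gap), by = chrom]
  dt[, grp := cumsum(newgrp)]
  tiles <- dt[, .(chrom = chrom[1L], start = min(pos) - 1L, end = max(pos),
                  n_dmcpgs = .N, mean_diff = mean(meth_diff),
                  mixed = length(unique(sign(meth_diff))) > 1L),
              by = grp]
  n_amb <- sum(tiles$mixed)
  tiles <- tiles[mixed == FALSE]
  # symmetric extension to min_size, clipped at 0
  w <- tiles$end - tiles$start
  deficit <- pmax(min_size - w, 0L)
  grow <- as.integer(ceiling(deficit / 2))
  ns <- tiles$start - grow
  ne <- tiles$end + grow
  over <- (ne - ns) - pmax(w, min_size)   # 1 when parity overshoots
  ne <- ne - pmax(over, 0L)
  push <- pmax(0L, -ns)                   # clipped at chromosome start
  ns <- ns + push; ne <- ne + push
  out <- data.table(chrom = tiles$chrom, start = as.integer(ns),
                    end = as.integer(ne), n_dmcpgs = tiles$n_dmcpgs,
                    mean_diff = tiles$mean_diff,
                    direction = fifelse(tiles$mean_diff > 0, "hyper", "hypo"))
  setorder(out, chrom, start, end)
  list(tiles = out[], n_ambiguous_removed = n_amb)
}

tiles_as_track <- function(tiles, track_name = "tiles") {
  interval_track(data.table(chrom = tiles$chrom, start = tiles$start,
                            end = tiles$end,
                            name = if ("category" %in% names(tiles))
                              tiles$category else tiles$direction,
                            score = tiles$mean_diff,
                            strand = "."),
                 track_name = track_name)
}

# does each row of `tiles` overlap (>= min_overlap_bp) any row of `other`?
tiles_found_in <- function(tiles, other, min_overlap_bp = 1L) {
  if (!nrow(tiles)) return(logical(0))
  if (!nrow(other)) return(rep(FALSE, nrow(tiles)))
  a <- copy(as.data.table(tiles))[, xid := .I][, .(chrom, start, end, xid)]
  b <- as.data.table(other)[, .(chrom, start, end)]
  setkey(b, chrom, start, end)
  ov <- foverlaps(a, b, by.x = c("chrom", "start", "end"),
                  type = "any", nomatch = NULL)
  ov <- ov[pmin(i.end, end) - pmax(i.start, start) >= min_overlap_bp]
  seq_len(nrow(tiles)) %in% ov$xid
}

# does each tile span contain >= 1 united CpG position of um?
tiles_have_data <- function(tiles, um) {
  if (!nrow(tiles)) return(logical(0))
  sites <- um$sites[, .(chrom, start = pos - 1L, end = pos)]
  setkey(sites, chrom, start, end)
  a <- copy(as.data.table(tiles))[, xid := .I][, .(chrom, start, end, xid)]
  ov <- foverlaps(a, sites, by.x = c("chrom", "start", "end"),
                  type = "any", nomatch = NULL)
  ov <- ov[pmin(i.end, end) - pmax(i.start, start) > 0L]
  seq_len(nrow(tiles)) %in% ov$xid
}

#' Classify DMR tiles as shared or family-specific
#'
#' Takes the tile sets of the three differential runs (all samples,
#' family A, family C) and the united matrices of the two family runs.
#' A tile is eligible only if its span contains at least one united CpG
#' position in BOTH family matrices (methylation data overlapped in both
#' families). "Found in" a run means >= `min_overlap_bp` bp overlap with
#' any tile of that run. Categories:
#' * family-specific: found in exactly one of the two family runs
#'   (with or without the all-samples run);
#' * shared: found in both family runs, or only in the all-samples run.
#'
#' @param run_all,run_A,run_C tile data.tables from [tile_dmrs()].
#' @param matrix_A,matrix_C `united_matrix` objects of the family runs.
#' @param min_overlap_bp overlap needed to count as "found in" (default 1).
#' @param cell_type label stored on the output (default "fibroblast").
#' @return data.table of eligible tiles (union of the three runs, with
#'   their source `run`) with a `category` column; ineligible tiles are
#'   dropped (attribute `n_ineligible`).
#' @export
classify_tiles <- function(run_all, run_A, run_C, matrix_A, matrix_C,
                           min_overlap_bp = 1L, cell_type = "fibroblast") {
  univ <- rbindlist(list(
    copy(as.data.table(run_all))[, run := "all"],
    copy(as.data.table(run_A))[, run := "familyA"],
    copy(as.data.table(run_C))[, run := "familyC"]), use.names = TRUE)
  if (!nrow(univ)) {
    univ[, `:=`(category = character(), cell_type = character())]
    setattr(univ, "n_ineligible", 0L)
    return(univ[])
  }
  eligible <- tiles_have_data(univ, matrix_A) & tiles_have_data(univ, matrix_C)
  out <- univ[eligible]
  setattr(out, "n_ineligible", sum(!eligible))
  if (!nrow(out)) {
    out[, `:=`(category = character(), cell_type = character())]
    return(out[])
  }
  fA <- tiles_found_in(out, run_A, min_overlap_bp)
  fC <- tiles_found_in(out, run_C, min_overlap_bp)
  fAll <- tiles_found_in(out, run_all, min_overlap_bp)
  out[, category := fifelse(fA & fC, "shared",
                    fifelse(fA, "familyA_specific",
                    fifelse(fC, "familyC_specific",
                    fifelse(fAll, "shared", "unclassified"))))]
  out[, cell_type := cell_type]
  out[]
}

#' Classify DMR persistence across cell types
#'
#' Labels each region (the union of fibroblast and iPSC tiles, deduplicated
#' by span) by its methylation state in the two cell types: (fibroblast
#' state x iPSC state) with state in hyper/hypo/none, excluding
#' (none, none) -- 8 classes, including the reversed classes hyper->hypo
#' and hypo->hyper. A region's state in a cell type is the direction of the
#' overlapping tile of that cell type with the largest overlap (none if no
#' overlap). Eligibility requires >= 1 united CpG position in both cell
#' types' matrices.
#'
#' @param fib_tiles,ipsc_tiles tile data.tables (with `direction`).
#' @param fib_matrix,ipsc_matrix `united_matrix` objects per cell type.
#' @return data.table: chrom, start, end, fib_state, ipsc_state,
#'   persistence (e.g. "hyper->none"); attribute `n_ineligible`.
#' @export
classify_persistence <- function(fib_tiles, ipsc_tiles,
                                 fib_matrix, ipsc_matrix) {
  regions <- unique(rbindlist(list(
    as.data.table(fib_tiles)[, .(chrom, start, end)],
    as.data.table(ipsc_tiles)[, .(chrom, start, end)]), use.names = TRUE))
  setorder(regions, chrom, start, end)
  if (!nrow(regions)) {
    regions[, `:=`(fib_state = character(), ipsc_state = character(),
                   persistence = character())]
    setattr(regions, "n_ineligible", 0L)
    return(regions[])
  }
  ok <- tiles_have_data(regions, fib_matrix) &
    tiles_have_data(regions, ipsc_matrix)
  out <- regions[ok]
  setattr(out, "n_ineligible", sum(!ok))
  state_in <- function(rg, tiles) {
    if (!nrow(rg)) return(character(0))
    st <- rep("none", nrow(rg))
    if (!nrow(tiles)) return(st)
    a <- copy(rg)[, xid := .I]
    b <- as.data.table(tiles)[, .(chrom, start, end, direction)]
    setkey(b, chrom, start, end)
    ov <- foverlaps(a, b, by.x = c("chrom", "start", "end"),
                    type = "any", nomatch = NULL)
    ov[, width := pmin(i.end, end) - pmax(i.start, start)]
    ov <- ov[width > 0L]
    if (nrow(ov)) {
      setorder(ov, xid, -width, start)  # largest overlap, tie: leftmost
      best <- ov[!duplicated(xid)]
      st[best$xid] <- best$direction
    }
    st
  }
  out[, fib_state := state_in(out, fib_tiles)]
  out[, ipsc_state := state_in(out, ipsc_tiles)]
  out <- out[!(fib_state == "none" & ipsc_state == "none")]
  out[, persistence := paste0(fib_state, "->", ipsc_state)]
  out[]
}

#' Write DMR tiles as BED6+
#'
#' Columns: chrom, start, end, name (= category, or direction when
#' unclassified), score (= mean_diff), strand ("."), plus n_dmcpgs,
#' direction, cell_type.
#'
#' @param tiles tile data.table.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_tiles_bed <- function(tiles, path) {
  dt <- as.data.table(tiles)
  nm <- if ("category" %in% names(dt)) dt$category else dt$direction
  out <- data.table(chrom = dt$chrom, start = dt$start, end = dt$end,
                    name = nm, score = round(dt$mean_diff, 4), strand = ".",
                    n_dmcpgs = if ("n_dmcpgs" %in% names(dt)) dt$n_dmcpgs
                               else NA_integer_,
                    direction = dt$direction,
                    cell_type = if ("cell_type" %in% names(dt)) dt$cell_type
                                else NA_character_)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
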