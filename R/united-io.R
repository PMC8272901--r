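#' Write / read a united matrix
#'
#' Plain TSV: `#sample` comment lines carry sample metadata, then a header
#' `chrom pos meth.<id>... cov.<id>...` and one row per united CpG site.
#'
#' @param um a `united_matrix`.
#' @param path file path.
#' @return invisibly `path` (writer); a `united_matrix` (reader).
#' @export
write_united <- function(um, path) {
  stopifnot(inherits(um, "united_matrix"))
  con <- file(path, "w")
  writeLines(sprintf("#min_cov\t%d", um$min_cov), con)
  for (i in seq_len(nrow(um$samples)))
    writeLines(sprintf("#sample\t%s\t%s\t%s", um$samples$sample_id[i],
                       um$samples$family[i], um$samples$status[i]), con)
  close(con)
  dt <- data.table(chrom = um$sites$chrom, pos = um$sites$pos)
  ids <- colnames(um$meth)
  for (id in ids) dt[[paste0("meth.", id)]] <- um$meth[, id]
  for (id in ids) dt[[paste0("cov.", id)]] <- um$cov[, id]
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE,
         quote = FALSE)
  invisible(path)
}

#' @rdname write_united
#' @export
read_united <- function(path) {
  hdr <- readLines(path, n = 200L)
  meta <- hdr[startsWith(hdr, "#")]
  mc <- as.integer(strsplit(meta[startsWith(meta, "#min_cov")],
                            "\t")[[1L]][2L])
  srows <- strsplit(meta[startsWith(meta, "#sample")], "\t")
  samples <- data.table(
    sample_id = vapply(srows, `[`, "", 2L),
    family = vapply(srows, `[`, "", 3L),
    status = vapply(srows, `[`, "", 4L))
  dt <- fread(path, sep = "\t", skip = "chrom\tpos")
  ids <- samples$sample_id
  meth <- as.matrix(dt[, paste0("meth.", ids), with = FALSE])
  cov <- as.matrix(dt[, paste0("cov.", ids), with = FALSE])
  colnames(meth) <- ids; colnames(cov) <- ids
  structure(list(sites = dt[, .(chrom, pos)], meth = meth, cov = cov,
                 samples = samples, min_cov = mc),
            class = "united_matrix")
}

#' Subset a united matrix to a set of samples
#' @param um a `united_matrix`.
#' @param ids sample ids to keep (site set is unchanged: the complete-case
#'   filter was applied at unite time over the original sample set).
#' @return a `united_matrix`.
#' @export
united_subset <- function(um, ids) {
  miss <- setdiff(ids, um$samples$sample_id)
  if (length(miss)) stop("samples not in matrix: ",
                         paste(miss, collapse = ", "))
  structure(list(sites = um$sites,
                 meth = um$meth[, ids, drop = FALSE],
                 cov = um$cov[, ids, drop = FALSE],
                 samples = um$samples[match(ids, sample_id)],
                 min_cov = um$min_cov),
            class = "united_matrix")
}

#' Read a DMR tile table written by the pipeline
#' @param path TSV path with header chrom, start, end, n_dmcpgs,
#'   mean_diff, direction (and optionally run, category, cell_type).
#' @return data.table.
#' @export
read_tiles <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  setorder(dt, chrom, start, end)
  dt[]
}

#' Write a DMR tile table (TSV with header)
#' @param tiles tile data.table.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_tiles <- function(tiles, path) {
  fwrite(as.data.table(tiles), path, sep = "\t", quote = FALSE)
  invisible(path)
}
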