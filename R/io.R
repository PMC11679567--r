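# Serialization: CSV mirrors for human inspection, an RDS keyed-array
# container as the binary format (bit-exact round trips).

#' Write a region series or spatio-temporal map as CSV
#'
#' Long-by-frame layout: `frame, region, <c1>, <c2>, <c3>` where the channel
#' columns are R/G/B for a raw series and Y/U/V for a converted map.
#'
#' @param x an [rgb_region_series()] or [stmap()]
#' @param path output file
#' @export
write_stmap_csv <- function(x, path) {
  is_yuv <- inherits(x, "stmap")
  chn <- if (is_yuv) c("Y", "U", "V") else c("R", "G", "B")
  d <- dim(x$values)
  df <- data.frame(
    frame = rep(seq_len(d[1]), times = d[2]),
    region = rep(x$region_labels, each = d[1]),
    c1 = as.numeric(x$values[, , 1]),
    c2 = as.numeric(x$values[, , 2]),
    c3 = as.numeric(x$values[, , 3]))
  names(df)[3:5] <- chn
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_stmap_csv()]
#'
#' @param path input file
#' @param fps frame rate of the series (not stored in the CSV)
#' @return an [rgb_region_series()] (R/G/B columns) or un-normalized
#'   [stmap()] (Y/U/V columns)
#' @export
read_stmap_csv <- function(path, fps) {
  df <- utils::read.csv(path, check.names = FALSE)
  is_yuv <- all(c("Y", "U", "V") %in% names(df))
  chn <- if (is_yuv) c("Y", "U", "V") else c("R", "G", "B")
  assert_that(all(c("frame", "region", chn) %in% names(df)),
              "CSV must have columns frame, region and %s",
              paste(chn, collapse = "/"))
  regions <- unique(df$region)
  nT <- max(df$frame)
  vals <- array(NA_real_, c(nT, length(regions), 3))
  for (j in seq_along(regions)) {
    sub <- df[df$region == regions[j], ]
    sub <- sub[order(sub$frame), ]
    for (c in 1:3) vals[, j, c] <- sub[[chn[c]]]
  }
  if (is_yuv) stmap(vals, fps = fps, normalized = FALSE,
                    region_labels = as.character(regions))
  else rgb_region_series(vals, fps = fps,
                         region_labels = as.character(regions))
}

#' Write a keyed-array container (binary, bit-exact round trip)
#'
#' @param x a pipeline object (`rgb_region_series`, `stmap`,
#'   `multiband_stack`, `synth_sample`, ...)
#' @param path output file
#' @export
write_container <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' Read a container written by [write_container()]
#' @param path input file
#' @return the stored object
#' @export
read_container <- function(path) readRDS(path)

#' Write a BVP trace as `(frame, bvp_value)` CSV
#' @param bvp a [bvp_signal()]
#' @param path output file
#' @export
write_bvp_csv <- function(bvp, path) {
  utils::write.csv(data.frame(frame = seq_along(bvp$values),
                              bvp_value = bvp$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a BVP CSV written by [write_bvp_csv()]
#' @param path input file
#' @param fps sampling rate
#' @return a [bvp_signal()]
#' @export
read_bvp_csv <- function(path, fps) {
  df <- utils::read.csv(path)
  bvp_signal(df$bvp_value[order(df$frame)], fps = fps)
}

#' Write a synthetic dataset to a directory
#'
#' One container file per sample plus `manifest.csv`.
#'
#' @param ds result of [gen_dataset()]
#' @param dir output directory (created if missing)
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in ds$samples)
    write_container(s, file.path(dir, sprintf("sample_%05d.rds", s$index)))
  utils::write.csv(ds$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir dataset directory
#' @return list with `samples` and `manifest`
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  samples <- lapply(manifest$index, function(i)
    read_container(file.path(dir, sprintf("sample_%05d.rds", i))))
  list(samples = samples, manifest = manifest)
}
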