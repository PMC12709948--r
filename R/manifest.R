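# Dataset manifests: a data frame with one row per paired sample
# (id, rgb, spectral, mask, split), stored as CSV.

#' Build a dataset manifest
#'
#' @param id character vector of sample identifiers.
#' @param rgb,spectral,mask file paths (spectral/mask may be `NA` for
#'   unlabeled or RGB-only samples).
#' @param split optional character vector `"train"`/`"test"`.
#' @return a `data.frame` of class `vegsr_manifest`.
#' @export
manifest <- function(id, rgb, spectral = NA_character_,
                     mask = NA_character_, split = NA_character_) {
  m <- data.frame(id = as.character(id), rgb = rgb,
                  spectral = spectral, mask = mask, split = split,
                  stringsAsFactors = FALSE)
  class(m) <- c("vegsr_manifest", "data.frame")
  m
}

#' Read / write a manifest CSV
#'
#' @param path CSV path.
#' @param check if `TRUE`, verify every listed file exists.
#' @return `read_manifest()` returns the manifest; `write_manifest()`
#'   returns `path` invisibly.
#' @export
read_manifest <- function(path, check = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "rgb", "spectral", "mask", "split")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  base <- dirname(path)
  for (col in c("rgb", "spectral", "mask")) {
    rel <- !is.na(m[[col]]) & nzchar(m[[col]]) & !file.exists(m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
    if (check) {
      bad <- !is.na(m[[col]]) & nzchar(m[[col]]) & !file.exists(m[[col]])
      if (any(bad)) stop("missing files in manifest: ",
                         paste(utils::head(m[[col]][bad], 3), collapse = ", "))
    }
  }
  class(m) <- c("vegsr_manifest", "data.frame")
  m
}

#' @rdname read_manifest
#' @param m a manifest.
#' @export
write_manifest <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' Split a manifest into train and test sets
#'
#' Deterministic under `(seed, row order)`: the same seed always yields the
#' same partition.  The train set has `round(ratio * n)` samples; the split
#' is exact (no overlap, full coverage) and both sides must be non-empty.
#'
#' @param m a manifest (or any data frame).
#' @param ratio train fraction, strictly between 0 and 1 (default 0.9,
#'   the conventional 9:1 split).
#' @param seed integer seed.
#' @return the manifest with its `split` column filled in.
#' @export
split_dataset <- function(m, ratio = 0.9, seed = 1L) {
  n <- nrow(m)
  if (n == 0L) stop("cannot split an empty manifest")
  if (!(ratio > 0 && ratio < 1)) stop("`ratio` must be strictly inside (0, 1)")
  n_train <- round(ratio * n)
  if (n_train == 0L || n_train == n)
    stop("split would leave an empty train or test set (n = ", n,
         ", ratio = ", ratio, ")")
  idx <- with_seed(seed, sample.int(n, n_train))
  m$split <- "test"
  m$split[idx] <- "train"
  m
}

#' Load a manifest's rasters into memory
#'
#' @param m a manifest with file paths.
#' @param split optional: restrict to `"train"` or `"test"` rows.
#' @return a list of samples, each a list with elements `rgb`
#'   ([rgb_image()]), `spectral` ([spectral_image()] or `NULL`), `mask`
#'   ([binary_mask()] or `NULL`), `id`, `split`.
#' @export
load_dataset <- function(m, split = NULL) {
  if (!is.null(split)) m <- m[m$split %in% split, , drop = FALSE]
  lapply(seq_len(nrow(m)), function(i) {
    row <- m[i, ]
    list(
      id = row$id,
      rgb = read_rgb(row$rgb),
      spectral = if (!is.na(row$spectral) && nzchar(row$spectral))
        read_spectral(row$spectral) else NULL,
      mask = if (!is.na(row$mask) && nzchar(row$mask))
        read_mask(row$mask) else NULL,
      split = row$split
    )
  })
}
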