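#' Split-then-augment dataset construction
#'
#' Builds a YOLO-layout detection dataset from synthetic Fv/Fm drought
#' scenes under the "first division, then enhancement" protocol: the
#' originals are split into train/test/validation FIRST, and every original
#' is then expanded to `1 + per_image_variants` images inside its own split,
#' so no source image ever contributes to two splits (objective independence
#' of test and validation). A JSON lineage manifest records, for every file,
#' its source scene, split, variant index and augmentation.
#'
#' @param dir output directory (created). The tree is
#'   `images/{train,test,val}`, `labels/{train,test,val}`, `dataset.yaml`,
#'   `manifest.json`.
#' @param n_originals number of original scenes (default 324).
#' @param val_frac fraction of originals held out for validation (default
#'   0.2; applied first, rounded to the nearest integer).
#' @param train_test_ratio length-2 ratio splitting the remaining originals
#'   into train and test (default `c(8, 2)`; train share floored).
#' @param per_image_variants augmented variants per original (default 12, so
#'   each original yields 13 images including itself).
#' @param seed RNG seed for grades, splits and augmentation draws.
#' @param spec a [scene_spec()]; its `side` sets the image resolution.
#' @param materialize if `TRUE`, render and write PNG images (slow at full
#'   resolution); if `FALSE` (default) only labels, the dataset YAML and the
#'   manifest are written, and images can be rendered later from the
#'   manifest's seeds.
#' @return object of class `drought_dataset`: list with `dir`, `counts`
#'   (images per split), `manifest` (data frame), `splits` (source ids).
#' @examples
#' \donttest{
#' ds <- build_dataset(tempfile("ds"), n_originals = 12, per_image_variants = 2,
#'                     seed = 1, spec = scene_spec(side = 64))
#' ds$counts
#' }
#' @export
build_dataset <- function(dir, n_originals = 324L, val_frac = 0.2,
                          train_test_ratio = c(8, 2),
                          per_image_variants = 12L, seed = 7L,
                          spec = scene_spec(), materialize = FALSE) {
  stopifnot(n_originals >= 3, val_frac > 0, val_frac < 1,
            length(train_test_ratio) == 2L, all(train_test_ratio > 0),
            per_image_variants >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n_val <- round(val_frac * n_originals)
  n_rest <- n_originals - n_val
  n_train <- floor(n_rest * train_test_ratio[1L] / sum(train_test_ratio))
  n_test <- n_rest - n_train
  if (min(n_val, n_train, n_test) < 1) stop("a split would be empty")

  ids <- sample.int(n_originals)
  split_of <- character(n_originals)
  split_of[ids[seq_len(n_val)]] <- "val"
  split_of[ids[n_val + seq_len(n_train)]] <- "train"
  split_of[ids[n_val + n_train + seq_len(n_test)]] <- "test"

  # balanced grade assignment across originals
  levels <- sample(rep_len(1:4, n_originals))
  scene_seeds <- sample.int(.Machine$integer.max - 1L, n_originals)

  for (s in c("train", "test", "val")) {
    dir.create(file.path(dir, "images", s), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "labels", s), recursive = TRUE, showWarnings = FALSE)
  }

  records <- vector("list", n_originals * (1L + per_image_variants))
  r <- 0L
  for (i in seq_len(n_originals)) {
    geom <- local({ set.seed(scene_seeds[i]); sample_scene_geometry(spec, levels[i]) })
    img <- NULL
    if (materialize) {
      set.seed(scene_seeds[i] + 1L)
      img <- render_scene(spec, geom$leaves)
    }
    s <- split_of[i]
    base <- sprintf("scene%04d", i)
    variants <- c(list(NULL), lapply(seq_len(per_image_variants),
                                     function(v) random_augment_op()))
    aug_seeds <- sample.int(.Machine$integer.max - 1L, length(variants))
    for (v in seq_along(variants)) {
      op <- variants[[v]]
      stem <- if (v == 1L) base else sprintf("%s_v%02d", base, v - 1L)
      labels <- geom$labels
      if (!is.null(op) && op$kind == "d4")
        labels <- d4_labels(labels, op$params$element)
      write_yolo_labels(labels, file.path(dir, "labels", s, paste0(stem, ".txt")))
      if (materialize) {
        set.seed(aug_seeds[v])
        out_img <- if (is.null(op)) img else augment(img, geom$labels, op)$image
        save_image(out_img, file.path(dir, "images", s, paste0(stem, ".png")))
      }
      r <- r + 1L
      records[[r]] <- data.frame(
        file = paste0(stem, ".png"), split = s, source_id = i,
        variant = v - 1L, level = levels[i],
        op = if (is.null(op)) "none" else op$kind,
        scene_seed = scene_seeds[i], aug_seed = aug_seeds[v])
    }
  }
  manifest <- do.call(rbind, records)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(list(path = normalizePath(dir, mustWork = FALSE),
                        train = "images/train", val = "images/val",
                        test = "images/test", nc = 4L,
                        names = as.list(grade_class_names())),
                   file.path(dir, "dataset.yaml"))
  counts <- table(manifest$split)[c("train", "test", "val")]
  structure(list(dir = dir,
                 counts = c(train = unname(counts["train"]),
                            test = unname(counts["test"]),
                            val = unname(counts["val"]),
                            total = nrow(manifest)),
                 manifest = manifest,
                 splits = split(seq_len(n_originals), split_of)),
            class = "drought_dataset")
}

#' @export
print.drought_dataset <- function(x, ...) {
  cat("Synthetic drought-stress detection dataset\n")
  cat(sprintf("  directory: %s\n", x$dir))
  cat(sprintf("  images: train %d / test %d / val %d (total %d)\n",
              x$counts["train"], x$counts["test"], x$counts["val"],
              x$counts["total"]))
  invisible(x)
}

#' Check a manifest for source leakage across splits
#'
#' Verifies the split-then-augment guarantee mechanically: every source scene
#' id must appear in exactly one split.
#'
#' @param manifest a manifest data frame (from [build_dataset()] or read back
#'   from `manifest.json`).
#' @return `TRUE` invisibly; errors if any source spans two splits.
#' @export
check_leakage_free <- function(manifest) {
  spl <- tapply(manifest$split, manifest$source_id,
                function(s) length(unique(s)))
  if (any(spl > 1L))
    stop("leakage: source(s) ",
         paste(names(spl)[spl > 1L], collapse = ", "),
         " appear in more than one split")
  invisible(TRUE)
}
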