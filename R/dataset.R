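#' Build a default phantom corpus configuration
#'
#' One [phantom_config()] per series, cycling over the seven view classes
#' with per-series seeds and mildly varied frame counts (25-40 frames at
#' full scale). Splits are assigned per view in the order
#' train / validation / test.
#'
#' @param per_view Series per view class.
#' @param split Integer vector `c(train, val, test)` per view; must sum to
#'   `per_view`.
#' @param matrix Phantom matrix size.
#' @param n_frames Frame count, or `NULL` to cycle over 25-40.
#' @param seed Base seed; series i of view v gets a distinct derived seed.
#' @return List of `phantom_config` objects with `$split` tags attached.
#' @export
corpus_configs <- function(per_view = 4L, split = c(per_view - 2L, 1L, 1L),
                           matrix = 160L, n_frames = NULL, seed = 1L) {
  if (sum(split) != per_view) stop("split must sum to per_view", call. = FALSE)
  views <- phantom_views()
  tags <- rep(c("train", "val", "test"), times = split)
  out <- list()
  for (v in seq_along(views)) {
    for (i in seq_len(per_view)) {
      nf <- if (is.null(n_frames)) c(25L, 28L, 32L, 36L, 40L)[(i - 1L) %% 5L + 1L]
            else as.integer(n_frames)
      cfg <- phantom_config(view_class = views[v], n_frames = nf,
                            matrix = matrix,
                            seed = seed + 1000L * v + i)
      cfg$split <- tags[i]
      out[[length(out) + 1L]] <- cfg
    }
  }
  out
}

#' Build a paired training dataset by retrospective undersampling
#'
#' Generates every configured phantom, degrades it with the tiny
#' golden-angle radial pipeline, and pairs aliased input with ground
#' truth. In `"specific"` mode every series is degraded at the same
#' spoke count; in `"generic"` mode each series draws its spoke count
#' uniformly from `spokes_set` (seeded), emulating training with randomly
#' varying acceleration.
#'
#' @param configs List of `phantom_config` objects (see [corpus_configs()]),
#'   each optionally carrying a `$split` tag.
#' @param mode `"specific"` or `"generic"`.
#' @param spokes Spoke count for specific mode.
#' @param spokes_set Candidate spoke counts for generic mode (default the
#'   six studied rates 13-33).
#' @param crop Center-crop size applied to both members of each pair
#'   (`NULL` to skip).
#' @param seed Seed for the generic-mode rate draw.
#' @param params Optional [sequence_params()] override for degradation.
#' @return List of `paired_sample` objects: fields `input`, `target`
#'   (both `cine_series`), `accel` (see [acceleration_spec()]), `split`,
#'   `view`.
#' @export
build_dataset <- function(configs, mode = c("specific", "generic"),
                          spokes = 17L, spokes_set = c(13L, 17L, 21L, 25L, 29L, 33L),
                          crop = NULL, seed = 1L, params = NULL) {
  mode <- match.arg(mode)
  if (length(configs) == 0L) stop("empty config list", call. = FALSE)
  rates <- if (mode == "specific") rep(as.integer(spokes), length(configs))
           else local({ set.seed(seed)
                        sample(as.integer(spokes_set), length(configs), replace = TRUE) })
  out <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    gt <- generate_cine(cfg)
    if (!is.null(crop)) gt <- normalize_series(center_crop(gt, crop))
    S <- rates[i]
    sp <- if (is.null(params))
      sequence_params(n_samples = 2L * dim(gt$frames)[1], spokes_per_frame = S)
      else params
    aliased <- degrade_series(gt, S, params = sp)
    out[[i]] <- structure(list(
      input = aliased, target = gt,
      accel = acceleration_spec(S, sp),
      split = if (is.null(cfg$split)) "train" else cfg$split,
      view = cfg$view_class, seed = cfg$seed),
      class = "paired_sample")
  }
  out
}

#' Subset a paired dataset by split tag
#' @param dataset List of `paired_sample`s.
#' @param split One of "train", "val", "test".
#' @return Filtered list.
#' @export
dataset_split <- function(dataset, split) {
  Filter(function(s) identical(s$split, split), dataset)
}

#' Leave-one-orientation-out split
#'
#' Removes every series of the left-out view from train/val and restricts
#' the test set to that view, for the unseen-orientation generalization
#' experiment.
#'
#' The returned components partition the dataset: `train` and `val` are
#' the train/val-tagged series of the kept views, `test` the test-tagged
#' series of the left-out view (so the comparison against a network
#' trained on all orientations stays fair: its training data never
#' overlaps the test set), and `unused` the remainder (left-out train/val
#' and kept-view test series).
#'
#' @param dataset List of `paired_sample`s with `$view` labels.
#' @param left_out_view View class to hold out.
#' @return List with `train`, `val`, `test`, `unused`.
#' @export
loo_split <- function(dataset, left_out_view) {
  views <- unique(vapply(dataset, function(s) s$view, character(1)))
  if (!left_out_view %in% views)
    stop(sprintf("unknown view label '%s'", left_out_view), call. = FALSE)
  kept <- vapply(dataset, function(s) s$view != left_out_view, logical(1))
  tag <- vapply(dataset, function(s) s$split, character(1))
  list(train  = dataset[kept & tag == "train"],
       val    = dataset[kept & tag == "val"],
       test   = dataset[!kept & tag == "test"],
       unused = dataset[(kept & tag == "test") | (!kept & tag != "test")])
}
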