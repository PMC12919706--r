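# ------------------------------------------------------------------
# Training with grid-adaptive sampling, validation-driven grid
# selection, inference and evaluation.
# ------------------------------------------------------------------

#' Full registration run configuration
#'
#' @param network a `network_config`
#' @param loss a `loss_weights`
#' @param upsampler an `upsampler_config`
#' @param grid_candidates list of candidate grid sizes; during adaptive
#'   training one is drawn uniformly per step
#' @param adaptive sample the grid size per step; if `FALSE` the first
#'   candidate is used throughout
#' @param epochs,batch_size,learning_rate Adam optimization settings
#' @param seed master RNG seed for sampling and batching
#' @return a `registration_config`
#' @export
registration_config <- function(network = network_config(),
                                loss = loss_weights(),
                                upsampler = upsampler_config(),
                                grid_candidates = list(
                                  c(5L, 5L, 5L), c(8L, 8L, 8L),
                                  c(10L, 10L, 10L), c(15L, 15L, 15L)),
                                adaptive = TRUE, epochs = 300L,
                                batch_size = 4L, learning_rate = 1e-4,
                                seed = 1L) {
  if (length(grid_candidates) < 1L) stop("grid_candidates must be nonempty")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(network = network, loss = loss, upsampler = upsampler,
                 grid_candidates = grid_candidates,
                 adaptive = isTRUE(adaptive), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "registration_config")
}

#' Desk-scale training profile
#'
#' The configuration the package uses for its 32^3 synthetic studies: the
#' reduced architecture with local attention over 8^3 tokens and a
#' displacement-head gain of 5, single-pair batches and a larger Adam
#' step than the clinical default. A from-scratch desk-scale run sees only
#' a few hundred optimization steps, so the profile trades the clinical
#' settings for ones that learn a transferable field in that budget.
#'
#' @param epochs training epochs (default 10)
#' @param seed RNG seed
#' @param ... further overrides passed to [registration_config()]
#' @return a `registration_config`
#' @export
desk_training_config <- function(epochs = 10L, seed = 1L, ...) {
  registration_config(
    network = small_network_config(local_radius = 0.35,
                                   proj_spatial = c(8L, 8L, 8L),
                                   head_gain = 5, seed = seed),
    epochs = epochs, batch_size = 1L, learning_rate = 1e-3, seed = seed,
    ...)
}

#' Draw a grid size uniformly from the candidate set
#'
#' @param config a `registration_config`
#' @return one grid-size vector
#' @export
draw_grid_size <- function(config) {
  config$grid_candidates[[sample.int(length(config$grid_candidates), 1L)]]
}

as_pairs <- function(x) {
  if (is.character(x)) read_synth_dataset(x) else x
}

# loss graph for one pair at one grid size; weights are param nodes
pair_loss <- function(pair, grid_size, config, weights_nodes, tape) {
  out <- gridreg_forward(pair$fixed, pair$moving, grid_size,
                         config$network, weights_nodes,
                         upsampler = config$upsampler, tape = tape)
  lw <- config$loss
  if (config$network$bayesian) {
    samples <- sample_transform_node(out$bayes$mean, out$bayes$var,
                                     lw$mc_samples)
    lu <- uncertainty_loss(pair$moving, pair$fixed, samples, out$bayes$var,
                           config$upsampler, lw)
  } else {
    lu <- similarity_image(ad_warp(as_arr(pair$moving), out$dense),
                           pair$fixed)
  }
  masks <- !is.null(pair$fixed_mask)
  ld <- if (masks)
    dice_loss(pair$fixed_mask,
              ad_warp(as_arr(pair$moving_mask), out$dense), lw$dice_eps)
  lb <- bending_energy(out$dense)
  total_loss(lu, if (masks) ld else NULL, lb, lw, masks_available = masks)
}

#' Train the registration network
#'
#' Per step, a batch of pairs is drawn and, in adaptive mode, a grid
#' size is sampled uniformly from the candidates; the weighted total
#' loss is backpropagated and Adam updates the weights. Loss components
#' and the drawn grid are logged per step. With validation pairs the
#' checkpoint keeps the best-validation weights next to the last ones.
#'
#' @param pairs list of pair lists (see [make_pair()]) or a dataset
#'   directory written by [write_synth_dataset()]
#' @param config a `registration_config`
#' @param val_pairs optional validation pairs (or directory)
#' @param log_file optional CSV path for the step log
#' @param verbose print per-epoch progress
#' @return a checkpoint: list with `weights` (best validation, or last),
#'   `last_weights`, `config`, `history` (step log data.frame),
#'   `best_val`
#' @export
train <- function(pairs, config = registration_config(), val_pairs = NULL,
                  log_file = NULL, verbose = FALSE) {
  pairs <- as_pairs(pairs)
  if (length(pairs) == 0L) stop("empty dataset")
  if (!is.null(val_pairs)) val_pairs <- as_pairs(val_pairs)
  weights <- init_weights(config$network)
  st <- adam_state(weights)
  hist <- list()
  best_val <- Inf
  best_weights <- weights
  with_local_seed(config$seed, {
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      idx <- sample(length(pairs))
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      for (b in batches) {
        step <- step + 1L
        gs <- if (config$adaptive) draw_grid_size(config)
              else config$grid_candidates[[1L]]
        tp <- ad_tape()
        wn <- lapply(weights, function(w) ad_param(tp, w))
        tot <- NULL
        comp <- c(u = 0, d = 0, bnd = 0)
        for (i in b) {
          rep_i <- pair_loss(pairs[[i]], gs, config, wn, tp)
          comp <- comp + c(rep_i$uncertainty_term, rep_i$dice_term,
                           rep_i$bending_term)
          tot <- if (is.null(tot)) rep_i$total_node
                 else ad_add(tot, rep_i$total_node)
        }
        tot <- ad_scale(tot, 1 / length(b))
        lv <- val(tot)
        if (!is.finite(lv))
          stop("NaN/Inf loss at step ", step, " (grid ",
               paste(gs, collapse = "x"), "); aborting")
        ad_backward(tp, tot)
        grads <- lapply(wn, function(n) n$grad)
        up <- adam_update(st, weights, grads, config$learning_rate)
        st <- up$state
        weights <- up$params
        hist[[step]] <- data.frame(step = step, epoch = ep,
                                   grid = gs[1], loss = lv,
                                   uncertainty = comp[["u"]] / length(b),
                                   dice = comp[["d"]] / length(b),
                                   bending = comp[["bnd"]] / length(b))
      }
      if (!is.null(val_pairs)) {
        vgrid <- config$grid_candidates[[ceiling(length(config$grid_candidates) / 2)]]
        vl <- mean(vapply(val_pairs, function(p) {
          out <- gridreg_forward(p$fixed, p$moving, vgrid, config$network,
                                 weights, upsampler = config$upsampler)
          similarity_image(warp(p$moving, out$dense), p$fixed)
        }, 1))
        if (vl < best_val) {
          best_val <- vl
          best_weights <- weights
        }
      }
      if (verbose)
        message(sprintf("epoch %d/%d loss %.5f", ep, config$epochs, lv))
    }
  })
  history <- do.call(rbind, hist)
  if (!is.null(log_file)) utils::write.csv(history, log_file, row.names = FALSE)
  structure(list(weights = if (is.finite(best_val)) best_weights else weights,
                 last_weights = weights, config = config, history = history,
                 best_val = if (is.finite(best_val)) best_val else NA_real_),
            class = "gridreg_checkpoint")
}

#' Save / load a checkpoint (weights + full configuration)
#'
#' @param ckpt a checkpoint from [train()]
#' @param path file path
#' @return `load_checkpoint` returns the checkpoint
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Select the grid size by validation metrics
#'
#' Every candidate grid is evaluated with the same weights on each
#' validation pair; the grid with the best mean metric wins (highest
#' Dice, or lowest centroid distance). Ties go to the coarsest grid.
#'
#' @param ckpt a checkpoint
#' @param val_pairs validation pairs (or directory) carrying masks
#'   (`dice`) or landmarks (`cd`)
#' @param metric `"dice"` or `"cd"`
#' @return the selected grid-size vector, with the per-candidate scores
#'   as attribute `"scores"`
#' @export
select_grid <- function(ckpt, val_pairs, metric = c("dice", "cd")) {
  metric <- match.arg(metric)
  val_pairs <- as_pairs(val_pairs)
  cands <- ckpt$config$grid_candidates
  if (metric == "dice" && is.null(val_pairs[[1]]$fixed_mask))
    stop("no validation masks available for Dice selection")
  if (metric == "cd" && is.null(val_pairs[[1]]$landmarks_fixed))
    stop("no validation landmarks available for CD selection")
  scores <- vapply(cands, function(gs) {
    mean(vapply(val_pairs, function(p) {
      out <- gridreg_forward(p$fixed, p$moving, gs, ckpt$config$network,
                             ckpt$weights, upsampler = ckpt$config$upsampler)
      if (metric == "dice") {
        wm <- warp(p$moving_mask, out$dense, "nearest")
        dice_coefficient(p$fixed_mask, wm)
      } else {
        wl <- warp_points(p$landmarks_moving, out$dense)
        centroid_distance(p$landmarks_fixed, wl, p$fixed$spacing)
      }
    }, 1))
  }, 1)
  ord <- order(vapply(cands, prod, 1))  # coarsest first; ties -> coarsest
  best <- if (metric == "dice") ord[which.max(scores[ord])]
          else ord[which.min(scores[ord])]
  structure(cands[[best]], scores = stats::setNames(
    scores, vapply(cands, function(g) paste(g, collapse = "x"), "")))
}

#' Register one pair with a trained checkpoint
#'
#' Deterministic inference: only the mean field warps the moving image;
#' the variance is upsampled for visualization.
#'
#' @param ckpt a checkpoint
#' @param fixed,moving `image_volume`s
#' @param grid_size grid to decode at (default: first candidate)
#' @param moving_mask optional mask to transport
#' @return list: `warped` (`image_volume`), `ddf` (`dense_field`),
#'   `variance` (per-voxel, or NULL without the Bayesian head),
#'   `jacobian` (`jacobian_stats`), `warped_mask`, `grid_size`
#' @export
register_pair <- function(ckpt, fixed, moving, grid_size = NULL,
                          moving_mask = NULL) {
  if (!identical(dim(as_arr(fixed)), dim(as_arr(moving))))
    stop("fixed/moving shape mismatch")
  if (is.null(grid_size)) grid_size <- ckpt$config$grid_candidates[[1L]]
  out <- gridreg_forward(fixed, moving, grid_size, ckpt$config$network,
                         ckpt$weights, upsampler = ckpt$config$upsampler)
  warped <- warp(moving, out$dense, "trilinear")
  varmap <- if (ckpt$config$network$bayesian)
    upsample(out$bayes$var, dim(as_arr(fixed)), ckpt$config$upsampler)
  list(warped = warped, ddf = dense_field(out$dense),
       variance = varmap,
       jacobian = jacobian_stats(out$dense, spacing = fixed$spacing %||% c(1, 1, 1)),
       warped_mask = if (!is.null(moving_mask))
         warp(moving_mask, out$dense, "nearest"),
       grid_size = grid_size)
}

#' File-based registration (NIfTI in, NIfTI + JSON out)
#'
#' @param ckpt checkpoint or path to one
#' @param fixed_path,moving_path input NIfTI files
#' @param out_prefix output path prefix; writes `<prefix>_warped.nii.gz`,
#'   `<prefix>_ddf.nii.gz`, `<prefix>_variance.nii.gz`,
#'   `<prefix>_metrics.json` (and `<prefix>_warped_mask.nii.gz` when a
#'   moving mask is given)
#' @param grid_size optional grid size
#' @param moving_mask_path optional moving-mask NIfTI to transport
#' @return invisibly, the `register_pair()` result
#' @export
register_files <- function(ckpt, fixed_path, moving_path, out_prefix,
                           grid_size = NULL, moving_mask_path = NULL) {
  if (is.character(ckpt)) ckpt <- load_checkpoint(ckpt)
  fixed <- read_volume(fixed_path)
  moving <- read_volume(moving_path)
  if (!isTRUE(all.equal(fixed$spacing, moving$spacing, tolerance = 1e-4)))
    stop("fixed/moving spacing mismatch")
  mmask <- if (!is.null(moving_mask_path))
    read_volume(moving_mask_path, mask = TRUE)
  res <- register_pair(ckpt, fixed, moving, grid_size, moving_mask = mmask)
  write_volume(res$warped, paste0(out_prefix, "_warped.nii.gz"))
  if (!is.null(res$warped_mask))
    write_volume(res$warped_mask, paste0(out_prefix, "_warped_mask.nii.gz"))
  write_volume(aperm(res$ddf$vectors, c(2, 3, 4, 1)),
               paste0(out_prefix, "_ddf.nii.gz"), spacing = fixed$spacing)
  if (!is.null(res$variance))
    write_volume(aperm(res$variance, c(2, 3, 4, 1)),
                 paste0(out_prefix, "_variance.nii.gz"),
                 spacing = fixed$spacing)
  js <- res$jacobian
  jsonlite::write_json(list(grid_size = res$grid_size,
                            logdet_mean = js$logdet_mean,
                            logdet_sd = js$logdet_sd,
                            folding_rate = js$folding_rate,
                            logdet_convention = js$logdet_convention),
                       paste0(out_prefix, "_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Evaluate registered cases against references
#'
#' @param cases list of per-case lists with elements `fixed_mask`,
#'   `warped_mask` (masks), optionally `landmarks_fixed`,
#'   `landmarks_warped`, and `ddf`; `spacing` defaults to 1 mm
#' @return data.frame of per-case Dice, centroid distances, |log det|
#'   and folding rate, with the aggregate mean and SD appended as
#'   attribute `"aggregate"`
#' @export
evaluate_cases <- function(cases) {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    sp <- cs$spacing %||% c(1, 1, 1)
    row <- data.frame(case = i, dice = NA_real_, cd_mask = NA_real_,
                      cd_landmark = NA_real_, logdet = NA_real_,
                      folding = NA_real_)
    if (!is.null(cs$fixed_mask) && !is.null(cs$warped_mask)) {
      row$dice <- dice_coefficient(cs$fixed_mask, cs$warped_mask)
      row$cd_mask <- centroid_distance(cs$fixed_mask, cs$warped_mask, sp)
    }
    if (!is.null(cs$landmarks_fixed) && !is.null(cs$landmarks_warped))
      row$cd_landmark <- centroid_distance(cs$landmarks_fixed,
                                           cs$landmarks_warped, sp)
    if (!is.null(cs$ddf)) {
      js <- jacobian_stats(cs$ddf, sp)
      row$logdet <- js$logdet_mean
      row$folding <- js$folding_rate
    }
    row
  })
  tab <- do.call(rbind, rows)
  agg <- rbind(mean = colMeans(tab[-1], na.rm = TRUE),
               sd = apply(tab[-1], 2, stats::sd, na.rm = TRUE))
  attr(tab, "aggregate") <- agg
  tab
}

#' Directory-based evaluation
#'
#' Pairs `<case>_warped_mask.nii.gz` / `_ddf.nii.gz` /
#' `_landmarks_warped.csv` under `pred_dir` with the matching
#' `_fixed_mask.nii.gz` / `_landmarks_fixed.csv` references under
#' `truth_dir`; missing cases are skipped with a warning. Results are
#' written as CSV and JSON into `pred_dir`.
#'
#' @param pred_dir predictions directory
#' @param truth_dir references directory
#' @return the [evaluate_cases()] data.frame
#' @export
evaluate <- function(pred_dir, truth_dir) {
  refs <- sort(list.files(truth_dir, pattern = "_fixed_mask\\.nii\\.gz$"))
  cases <- list()
  for (f in refs) {
    case <- sub("_fixed_mask\\.nii\\.gz$", "", f)
    wm <- file.path(pred_dir, paste0(case, "_warped_mask.nii.gz"))
    if (!file.exists(wm)) {
      warning("missing prediction for ", case, "; skipped")
      next
    }
    cs <- list(fixed_mask = read_volume(file.path(truth_dir, f), mask = TRUE),
               warped_mask = read_volume(wm, mask = TRUE))
    cs$spacing <- cs$fixed_mask$spacing
    dd <- file.path(pred_dir, paste0(case, "_ddf.nii.gz"))
    if (file.exists(dd)) {
      v <- read_ddf(dd)
      cs$ddf <- v
    }
    lf <- file.path(truth_dir, paste0(case, "_landmarks_fixed.csv"))
    lw <- file.path(pred_dir, paste0(case, "_landmarks_warped.csv"))
    if (file.exists(lf) && file.exists(lw)) {
      cs$landmarks_fixed <- read_landmarks(lf)
      cs$landmarks_warped <- read_landmarks(lw)
    }
    cases[[length(cases) + 1L]] <- cs
  }
  if (length(cases) == 0L) stop("no evaluable cases")
  tab <- evaluate_cases(cases)
  utils::write.csv(format(tab, digits = 6), file.path(pred_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(per_case = tab,
                            aggregate = as.data.frame(attr(tab, "aggregate"))),
                       file.path(pred_dir, "metrics.json"), digits = NA,
                       dataframe = "columns")
  tab
}

# read a 4D NIfTI displacement (W,H,D,3) back to (3,W,H,D)
read_ddf <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  dense_field(aperm(a, c(4, 1, 2, 3)))
}
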