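#' Training configuration
#'
#' Defaults follow the published genome-scale recipe: SGD with learning rate
#' 1e-6 and weight decay 1e-3, at most 30 epochs with early-stopping
#' patience 10, targets clipped to \[-16, 16\], augmentation drawing
#' 500-5000 cells and 400-1000 metacells per example plus a random +/-50bp
#' shift, training centers kept 4 Mb / 5 Mb away from the chromosome start /
#' end, chromosomes 3 and 15 for validation and 5, 18, 20, 21 held out.
#' Momentum (0.9) and batch size (1; per-example SGD) are unstated in the
#' recipe and are package choices. [miniature_train_config()] rescales the
#' learning rate and buffers for the desk-scale geometry.
#'
#' @param lr learning rate.
#' @param weight_decay L2 penalty coefficient.
#' @param momentum SGD momentum.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param clip target clip bounds.
#' @param cell_subsample range of cells drawn per training example.
#' @param metacell_subsample range of metacells drawn per training example.
#' @param shift_bp set of random track shifts (bp).
#' @param start_buffer,end_buffer distances from the chromosome start/end
#'   within which no training center may fall.
#' @param val_chroms,test_chroms chromosome name sets for validation and
#'   held-out testing.
#' @param batch_size examples per gradient step (gradients averaged).
#' @param both_sides train on both stripe sides of every sampled window
#'   (via input reversal, shared weights) instead of one random side.
#' @param examples_per_epoch cap on training examples per epoch.
#' @param val_examples cap on validation examples per epoch.
#' @param scale pseudobulk normalization scale.
#' @param seed RNG seed for the whole run.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-6, weight_decay = 1e-3, momentum = 0.9,
                         max_epochs = 30L, patience = 10L,
                         clip = c(-16, 16),
                         cell_subsample = c(500L, 5000L),
                         metacell_subsample = c(400L, 1000L),
                         shift_bp = c(-50L, 50L),
                         start_buffer = 4e6, end_buffer = 5e6,
                         val_chroms = c("chr3", "chr15"),
                         test_chroms = c("chr5", "chr18", "chr20", "chr21"),
                         batch_size = 8L, both_sides = TRUE,
                         examples_per_epoch = 200L, val_examples = 50L,
                         scale = 1e8, seed = 1L) {
  if (patience > max_epochs) stop("patience must be <= max_epochs")
  structure(list(lr = lr, weight_decay = weight_decay, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), clip = clip,
                 cell_subsample = cell_subsample,
                 metacell_subsample = metacell_subsample,
                 batch_size = as.integer(batch_size),
                 both_sides = isTRUE(both_sides),
                 shift_bp = shift_bp, start_buffer = start_buffer,
                 end_buffer = end_buffer, val_chroms = val_chroms,
                 test_chroms = test_chroms,
                 examples_per_epoch = examples_per_epoch,
                 val_examples = val_examples, scale = scale,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @param ... overrides passed to [train_config()].
#' @export
miniature_train_config <- function(...) {
  defaults <- list(lr = 1e-3, max_epochs = 20L, patience = 5L,
                   start_buffer = 2.5e5, end_buffer = 2.5e5,
                   examples_per_epoch = 100L, val_examples = 20L,
                   both_sides = FALSE,
                   val_chroms = "chrV", test_chroms = "chrT")
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

#' Usable training centers of a chromosome
#'
#' Contact bins whose span lies at least `start_buffer` after the chromosome
#' start and `end_buffer` before its end.
#'
#' @param dataset a [contact_dataset()].
#' @param config a [train_config()].
#' @return integer vector of center bins.
#' @export
usable_centers <- function(dataset, config) {
  res <- dataset$zmap$resolution
  len <- chrom_length(dataset$layout, dataset$chrom)
  t_min <- as.integer(ceiling(config$start_buffer / res)) + 1L
  t_max <- as.integer(floor((len - config$end_buffer) / res))
  if (t_min > t_max) return(integer())
  t_min:t_max
}

#' Build one (augmented) training example
#'
#' Pseudobulk is recomputed from a fresh random cell subsample, the
#' co-accessibility slice from a fresh metacell subsample, and the
#' accessibility/CTCF windows are shifted by a random element of `shift_bp`
#' (the 500bp co-accessibility grid cannot represent a 50bp shift, so the
#' slice is left unshifted). The target is the clipped, masked one-sided
#' V-stripe at `t`. With `augment = FALSE` the full population and a zero
#' shift are used (validation and inference).
#'
#' @param dataset a [contact_dataset()].
#' @param t center contact bin.
#' @param geometry a [model_geometry()].
#' @param config a [train_config()].
#' @param augment draw random subsamples and shift?
#' @param side `"right"`, `"left"`, or NULL to draw at random.
#' @return a window example: list with `acc_ctcf`, `coacc`, `target`, `t`,
#'   `side`, `chrom`.
#' @export
make_training_example <- function(dataset, t, geometry, config,
                                  augment = TRUE, side = NULL,
                                  draws = NULL) {
  centers <- usable_centers(dataset, config)
  if (augment && !(t %in% centers))
    stop("center ", t, " falls inside the start/end buffer")
  if (is.null(draws)) draws <- augmentation_draws(dataset, config, augment)
  pb <- draws$pb
  mc_idx <- draws$mc_idx
  shift <- draws$shift
  shift_bins <- as.integer(shift / geometry$acc_resolution)
  acc <- extract_window(pb$values, t, geometry,
                        resolution = geometry$acc_resolution,
                        shift_bins = shift_bins)
  ctcf <- extract_window(dataset$ctcf$values, t, geometry,
                         resolution = geometry$acc_resolution,
                         shift_bins = shift_bins)
  coacc <- coaccess_slice(dataset$profiles, t, geometry, metacells = mc_idx)
  if (is.null(side))
    side <- if (augment) sample(c("right", "left"), 1L) else "right"
  target <- if (!is.null(dataset$zmap))
    target_vstripe(dataset$zmap, t, side, dataset$mask,
                   max_d = geometry$max_distance_bins) else NULL
  list(acc_ctcf = cbind(acc, ctcf), coacc = coacc, target = target,
       t = t, side = side, chrom = dataset$chrom)
}

#' Augmentation draws for one training iteration
#'
#' One cell subsample (as a pseudobulk track), one metacell subsample and one
#' track shift, drawn per optimizer iteration and shared by the examples of
#' that batch.
#'
#' @param dataset a [contact_dataset()].
#' @param config a [train_config()].
#' @param augment draw random subsamples (TRUE) or use the full population?
#' @return list with `pb` (pseudobulk `bin_track`), `mc_idx`, `shift`.
#' @export
augmentation_draws <- function(dataset, config, augment = TRUE) {
  n_cells <- nrow(dataset$acc_counts)
  cell_idx <- if (augment)
    subsample_for_augmentation(n_cells, config$cell_subsample)
  else seq_len(n_cells)
  pb <- pseudobulk_from_matrix(dataset$acc_counts, cell_idx, dataset$chrom,
                               50L, scale = config$scale)
  n_mc <- length(dataset$metacells$members)
  mc_idx <- if (augment)
    subsample_for_augmentation(n_mc, config$metacell_subsample)
  else NULL
  shift <- if (augment) sample(config$shift_bp, 1L) else 0L
  list(pb = pb, mc_idx = mc_idx, shift = shift)
}

#' Masked mean squared error
#'
#' MSE over the valid entries of a V-stripe target; an all-invalid target
#' contributes 0 (with `n_valid = 0` recorded in the attribute).
#'
#' @param pred numeric prediction vector.
#' @param target a [target_vstripe()] result (or list with `values`,
#'   `valid`).
#' @return scalar loss with attribute `n_valid`.
#' @export
masked_mse <- function(pred, target) {
  v <- target$valid
  if (length(pred) != length(v)) stop("prediction/target length mismatch")
  n <- sum(v)
  loss <- if (n == 0) 0 else mean((pred[v] - target$values[v])^2)
  attr(loss, "n_valid") <- n
  loss
}

masked_mse_grad <- function(pred, target) {
  v <- target$valid
  g <- numeric(length(pred))
  n <- sum(v)
  if (n > 0) g[v] <- 2 * (pred[v] - target$values[v]) / n
  g
}

train_chrom_names <- function(datasets, config) {
  setdiff(names(datasets), c(config$val_chroms, config$test_chroms))
}

# evenly spaced validation centers, deterministic
validation_centers <- function(datasets, config) {
  chroms <- intersect(names(datasets), config$val_chroms)
  out <- list()
  for (cn in chroms) {
    tt <- usable_centers(datasets[[cn]], config)
    if (!length(tt)) next
    n <- min(length(tt), config$val_examples)
    out[[cn]] <- tt[unique(as.integer(round(seq(1, length(tt),
                                                length.out = n))))]
  }
  out
}

validation_loss <- function(model, datasets, config, stage) {
  centers <- validation_centers(datasets, config)
  tot <- 0; n <- 0L
  for (cn in names(centers)) {
    ds <- datasets[[cn]]
    for (t in centers[[cn]]) {
      ex <- make_training_example(ds, t, model$geometry, config,
                                  augment = FALSE, side = "right")
      fw <- model_forward(model, ex$acc_ctcf, ex$coacc, stage = stage)
      l <- masked_mse(fw$pred, ex$target)
      if (attr(l, "n_valid") > 0) { tot <- tot + as.numeric(l); n <- n + 1L }
    }
  }
  if (n == 0) NA_real_ else tot / n
}

# shared optimization loop for the three training entry points
run_training <- function(model, datasets, config, stage,
                         frozen = character(), max_epochs = NULL,
                         early_stop = TRUE, augment = TRUE) {
  if (inherits(datasets, "contact_dataset"))
    datasets <- stats::setNames(list(datasets), datasets$chrom)
  max_epochs <- if (is.null(max_epochs)) config$max_epochs else max_epochs
  tr_chroms <- train_chrom_names(datasets, config)
  if (!length(tr_chroms)) stop("no training chromosomes in the dataset list")
  pool <- data.table::rbindlist(lapply(tr_chroms, function(cn) {
    data.table::data.table(chrom = cn,
                           t = usable_centers(datasets[[cn]], config))
  }))
  if (nrow(pool) == 0) stop("no usable training centers (buffers too wide?)")
  opt_state <- list()
  history <- data.table::data.table(epoch = integer(), train_loss = numeric(),
                                    val_loss = numeric())
  best_val <- Inf; best_params <- model$params; since_best <- 0L
  set.seed(config$seed)
  for (epoch in seq_len(max_epochs)) {
    n_ex <- min(nrow(pool), config$examples_per_epoch)
    idx <- sample.int(nrow(pool), n_ex)
    ep_loss <- 0; ep_n <- 0L
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    for (batch in batches) {
      acc_grads <- NULL; n_in_batch <- 0L
      # one augmentation draw per iteration (batch) and chromosome
      draws <- list()
      for (r in batch) {
        cn <- pool$chrom[r]
        ds <- datasets[[cn]]
        if (is.null(draws[[cn]]))
          draws[[cn]] <- augmentation_draws(ds, config, augment)
        ex <- make_training_example(ds, pool$t[r], model$geometry, config,
                                    augment = augment, side = "right",
                                    draws = draws[[cn]])
        # shared weights predict both stripe sides: train on each window's
        # right stripe and, via input reversal, its left stripe (or one
        # random side when both_sides is off)
        left_target <- target_vstripe(ds$zmap, pool$t[r], "left", ds$mask,
                                      max_d = model$geometry$max_distance_bins)
        rex <- reverse_example(ex)
        variants <- list(list(x = ex, target = ex$target),
                         list(x = rex, target = left_target))
        if (!config$both_sides) variants <- variants[sample(2L, 1L)]
        for (variant in variants) {
          fw <- model_forward(model, variant$x$acc_ctcf, variant$x$coacc,
                              stage = stage, keep_cache = TRUE,
                              cache_fe1 = !("fe1." %in% frozen))
          loss <- masked_mse(fw$pred, variant$target)
          if (!is.finite(loss))
            stop("training diverged (non-finite loss) at epoch ", epoch)
          if (attr(loss, "n_valid") == 0) next
          dpred <- masked_mse_grad(fw$pred, variant$target)
          grads <- model_backward(model, dpred, fw$cache,
                                  backprop_fe1 = !("fe1." %in% frozen))
          acc_grads <- add_grads(acc_grads, grads)
          n_in_batch <- n_in_batch + 1L
          ep_loss <- ep_loss + as.numeric(loss); ep_n <- ep_n + 1L
        }
      }
      if (n_in_batch == 0L) next
      acc_grads <- lapply(acc_grads, function(gx) gx / n_in_batch)
      st <- sgd_step(model$params, acc_grads, opt_state, lr = config$lr,
                     momentum = config$momentum,
                     weight_decay = config$weight_decay, frozen = frozen)
      model$params <- st$params; opt_state <- st$state
    }
    vl <- validation_loss(model, datasets, config, stage)
    history <- rbind(history,
                     data.table::data.table(epoch = epoch,
                                            train_loss = ep_loss / max(ep_n, 1L),
                                            val_loss = vl))
    if (early_stop && !is.na(vl)) {
      if (vl < best_val) {
        best_val <- vl; best_params <- model$params; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
  }
  if (early_stop && is.finite(best_val)) model$params <- best_params
  list(model = model, history = history, best_val = best_val)
}

# the target of a left-side example is predicted from the reversed input
reverse_example_with_target <- function(ex) {
  out <- reverse_example(ex)
  out$target <- ex$target
  out
}

#' Stage-1 training: feature extractor 1 with a dummy head
#'
#' Optimizes feature extractor 1 plus a dummy linear predictor against the
#' masked V-stripe targets, with early stopping on validation loss and
#' restoration of the best-validation parameters.
#'
#' @param model a [chromafold_model()].
#' @param datasets named list of [contact_dataset()] (names = chromosomes),
#'   or a single dataset.
#' @param config a [train_config()].
#' @return list with `model` and `history` (epoch, train/validation loss).
#' @export
train_stage1 <- function(model, datasets, config) {
  res <- run_training(model, datasets, config, stage = "stage1",
                      frozen = c("fe2.", "head.final"))
  res$model$trained_stages <- union(res$model$trained_stages, "stage1")
  res
}

#' Stage-2 training: feature extractor 2 and the final predictor
#'
#' Freezes feature extractor 1 (its parameters are bit-identical before and
#' after) and trains feature extractor 2 plus the final linear layer.
#'
#' @inheritParams train_stage1
#' @return list with `model` and `history`.
#' @export
train_stage2 <- function(model, datasets, config) {
  if (!"stage1" %in% model$trained_stages)
    stop("stage-1 training must run before stage 2")
  res <- run_training(model, datasets, config, stage = "full",
                      frozen = c("fe1.", "head.dummy"))
  res$model$trained_stages <- union(res$model$trained_stages, "stage2")
  res
}

#' Fine-tune a pretrained model on a mixed population
#'
#' All parameters trainable for exactly `epochs` epochs (default 1) on the
#' training chromosomes of the supplied paired bulk dataset; no early
#' stopping. Used to adapt the model before per-cluster deconvolution.
#'
#' @inheritParams train_stage1
#' @param epochs number of fine-tuning epochs (default 1).
#' @return list with `model` and `history`.
#' @export
finetune <- function(model, datasets, config, epochs = 1L) {
  if (!all(c("stage1", "stage2") %in% model$trained_stages))
    stop("finetune requires a model pretrained through stages 1 and 2")
  res <- run_training(model, datasets, config, stage = "full",
                      frozen = "head.dummy", max_epochs = epochs,
                      early_stop = FALSE)
  res$model$trained_stages <- union(res$model$trained_stages, "finetune")
  res
}
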