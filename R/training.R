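#' Training configuration
#'
#' Hyperparameters of the adversarial training protocol. Reference values:
#' 100 epochs for 2D models and 300 for 3D (where early stopping is used),
#' Adam with learning rate 0.002, first-moment decay 0.5, batch size 1;
#' background/foreground loss weights 0.2/0.8 for the Otsu-weighted
#' variant. The cycle-consistency weight (10) and the optional identity
#' and history-buffer terms follow this architecture family's conventions
#' and are off by default where the protocol does not mention them.
#'
#' @param epochs Training epochs (>= 1). 2D reference 100, 3D 300.
#' @param lr Adam learning rate.
#' @param beta1 Adam first-moment decay.
#' @param batch_size Patches per step (the protocol uses 1).
#' @param w_bg,w_fg Otsu background/foreground loss weights; must sum to 1.
#' @param lambda_cycle Cycle-consistency weight.
#' @param use_otsu_loss `TRUE` for the Otsu-weighted "+" variant, `FALSE`
#'   for the plain-MSE cycle loss.
#' @param identity_weight Weight of the optional identity-mapping loss
#'   (relative to `lambda_cycle`); 0 disables.
#' @param buffer_size Discriminator image-history buffer; 0 disables.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping; `Inf` disables (2D default); the 3D protocol enables it.
#' @param lr_decay_from Epoch after which the learning rate decays linearly
#'   to zero at the final epoch (this architecture family's convention for
#'   settling late-training oscillation); `NULL` keeps it constant.
#' @param seed Integer seed governing the whole run.
#' @return A `tg_train_config`.
#' @export
train_config <- function(epochs = 100L, lr = 0.002, beta1 = 0.5,
                         batch_size = 1L, w_bg = 0.2, w_fg = 0.8,
                         lambda_cycle = 10, use_otsu_loss = TRUE,
                         identity_weight = 0, buffer_size = 0L,
                         early_stop_patience = Inf, lr_decay_from = NULL,
                         seed = 1L) {
  stopifnot(epochs >= 1, lr > 0, beta1 > 0, beta1 < 1, batch_size >= 1,
            w_bg >= 0, w_fg >= 0, lambda_cycle >= 0, identity_weight >= 0,
            buffer_size >= 0, early_stop_patience > 0)
  if (abs(w_bg + w_fg - 1) > 1e-12) stop("w_bg + w_fg must equal 1")
  if (!is.null(lr_decay_from)) stopifnot(lr_decay_from >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 batch_size = as.integer(batch_size), w_bg = w_bg, w_fg = w_fg,
                 lambda_cycle = lambda_cycle, use_otsu_loss = use_otsu_loss,
                 identity_weight = identity_weight,
                 buffer_size = as.integer(buffer_size),
                 early_stop_patience = early_stop_patience,
                 lr_decay_from = lr_decay_from,
                 seed = as.integer(seed)),
            class = "tg_train_config")
}

epoch_lr <- function(config, epoch) {
  if (is.null(config$lr_decay_from) || epoch <= config$lr_decay_from) {
    return(config$lr)
  }
  span <- config$epochs - config$lr_decay_from + 1
  config$lr * max(0, 1 - (epoch - config$lr_decay_from) / span)
}

# ---- Adam ----------------------------------------------------------------

adam_step <- function(net, lr, beta1, beta2 = 0.999, eps = 1e-8) {
  for (l in net_layer_envs(net)) {
    if (is.null(l$opt$t)) l$opt$t <- 0L
    l$opt$t <- l$opt$t + 1L
    t <- l$opt$t
    for (nm in names(l$pars)) {
      g <- l$grads[[nm]]
      if (is.null(l$opt[[nm]])) l$opt[[nm]] <- list(m = g * 0, v = g * 0)
      st <- l$opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      l$opt[[nm]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l$pars[[nm]] <- l$pars[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(net)
}

check_patch_compat <- function(setA, setB) {
  if (!length(setA$patches) || !length(setB$patches)) {
    stop("both patch sets must be non-empty")
  }
  if (!identical(dim(setA$patches[[1]]), dim(setB$patches[[1]]))) {
    stop("incompatible patch shapes between domains: ",
         paste(dim(setA$patches[[1]]), collapse = "x"), " vs ",
         paste(dim(setB$patches[[1]]), collapse = "x"))
  }
}

finite_or_abort <- function(..., epoch, step) {
  v <- c(...)
  if (!all(is.finite(v))) {
    stop("non-finite loss at epoch ", epoch, ", step ", step,
         " (", paste(signif(v, 4), collapse = ", "),
         "); lower the learning rate or check the input normalization")
  }
}

# ---- Unpaired (two-generator / two-discriminator) training ---------------

#' Train an unpaired image-to-image translation model
#'
#' The two-generator / two-discriminator cycle-consistent scheme:
#' `G_AB` maps domain A to B and `G_BA` maps back; discriminator `D_B`
#' scores real vs generated B images (and `D_A` symmetrically); both
#' generators are driven by least-squares adversarial losses plus a
#' cycle-consistency reconstruction penalty, which is plain MSE or the
#' Otsu-weighted foreground/background MSE depending on
#' `config$use_otsu_loss`. Updates alternate generator/discriminator with
#' Adam at the configured settings, batch size 1, fully seeded.
#'
#' @param config A [train_config()].
#' @param setA,setB Training patch sets (normalized to `[-1, 1]`), equal
#'   patch geometry.
#' @param gen_spec,disc_spec Architecture token strings for the generators
#'   and discriminators (defaults: the 128-pixel-patch reference layouts).
#' @param disc_norm_first Instance-normalize the first discriminator block
#'   (the literal architecture reading). `FALSE` selects the family's
#'   conventional variant, which keeps first-layer intensity information —
#'   important when the two domains differ mainly in intensity polarity.
#' @param dims 2 or 3.
#' @param valA,valB Optional held-out patch sets; per-epoch validation
#'   cycle loss is recorded and drives early stopping.
#' @param eval_fn Optional `function(G_AB, G_BA) -> scalar` called after
#'   each epoch and recorded as `val_metric` in the history.
#' @param eval_higher_better Direction of `eval_fn` for early stopping.
#' @param checkpoint_dir If set, per-epoch checkpoints are written there.
#' @param verbose Print one line per epoch.
#' @return List of class `tg_cyclegan`: `G_AB`, `G_BA`, `D_A`, `D_B`,
#'   `history` (per-epoch loss data frame), `config`.
#' @export
train_unpaired <- function(config, setA, setB,
                           gen_spec = "c7s1-64, d128, d256, R256 (x6), u128, u64, c7s1-1",
                           disc_spec = "C64, C128, C256, C512, F1",
                           disc_norm_first = TRUE,
                           dims = 2L, valA = NULL, valB = NULL,
                           eval_fn = NULL, eval_higher_better = TRUE,
                           checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "tg_train_config"))
  check_patch_compat(setA, setB)
  set.seed(config$seed)
  G_AB <- build_generator(parse_arch_spec(gen_spec, dims, 1L, 1L))
  G_BA <- build_generator(parse_arch_spec(gen_spec, dims, 1L, 1L))
  D_A <- build_discriminator(parse_arch_spec(disc_spec, dims, 1L, 1L),
                             norm_first = disc_norm_first)
  D_B <- build_discriminator(parse_arch_spec(disc_spec, dims, 1L, 1L),
                             norm_first = disc_norm_first)
  cyc_mode <- if (config$use_otsu_loss) "otsu" else "mse"
  # Otsu masks of the cycle targets, cached once per patch
  maskA <- if (cyc_mode == "otsu") lapply(setA$patches, function(p) suppressWarnings(otsu_mask(p))) else NULL
  maskB <- if (cyc_mode == "otsu") lapply(setB$patches, function(p) suppressWarnings(otsu_mask(p))) else NULL

  nA <- length(setA$patches); nB <- length(setB$patches)
  n_steps <- max(nA, nB)
  bufA <- list(); bufB <- list()  # optional fake-image history buffers

  buf_push <- function(buf, img, size) {
    if (size <= 0) return(list(buf = buf, img = img))
    if (length(buf) < size) {
      buf[[length(buf) + 1L]] <- img
      return(list(buf = buf, img = img))
    }
    if (runif(1) > 0.5) {
      k <- sample.int(length(buf), 1)
      old <- buf[[k]]; buf[[k]] <- img
      return(list(buf = buf, img = old))
    }
    list(buf = buf, img = img)
  }

  hist_rows <- vector("list", config$epochs)
  best_val <- NA_real_; best_epoch <- 0L
  t0 <- proc.time()[["elapsed"]]

  for (epoch in seq_len(config$epochs)) {
    idxA <- sample(rep_len(seq_len(nA), n_steps))
    idxB <- sample(rep_len(seq_len(nB), n_steps))
    lr_e <- epoch_lr(config, epoch)
    acc <- c(adv_G = 0, adv_D = 0, cycle_A = 0, cycle_B = 0,
             total_G = 0, total_D = 0)
    for (s in seq_len(n_steps)) {
      a <- setA$patches[[idxA[s]]]
      b <- setB$patches[[idxB[s]]]
      ma <- if (!is.null(maskA)) maskA[[idxA[s]]] else NULL
      mb <- if (!is.null(maskB)) maskB[[idxB[s]]] else NULL

      zero_grads(G_AB); zero_grads(G_BA)

      # --- direction A -> B -> A ---
      fake_b <- net_forward(G_AB, a, train = TRUE)
      sc_fb <- net_forward(D_B, fake_b, train = TRUE)
      adv_g1 <- mean((sc_fb - 1)^2)
      zero_grads(D_B)
      g_fb_adv <- net_backward(D_B, adv_grad_g_fake(sc_fb))
      rec_a <- net_forward(G_BA, fake_b, train = TRUE)
      cycA <- cycle_loss(a, rec_a, cyc_mode, config$w_bg, config$w_fg, mask = ma)
      g_reca <- cycle_loss_grad(a, rec_a, cyc_mode, config$w_bg, config$w_fg,
                                mask = ma) * config$lambda_cycle
      g_fb_cyc <- net_backward(G_BA, g_reca)
      net_backward(G_AB, g_fb_adv + g_fb_cyc)

      # --- direction B -> A -> B ---
      fake_a <- net_forward(G_BA, b, train = TRUE)
      sc_fa <- net_forward(D_A, fake_a, train = TRUE)
      adv_g2 <- mean((sc_fa - 1)^2)
      zero_grads(D_A)
      g_fa_adv <- net_backward(D_A, adv_grad_g_fake(sc_fa))
      rec_b <- net_forward(G_AB, fake_a, train = TRUE)
      cycB <- cycle_loss(b, rec_b, cyc_mode, config$w_bg, config$w_fg, mask = mb)
      g_recb <- cycle_loss_grad(b, rec_b, cyc_mode, config$w_bg, config$w_fg,
                                mask = mb) * config$lambda_cycle
      g_fa_cyc <- net_backward(G_AB, g_recb)
      net_backward(G_BA, g_fa_adv + g_fa_cyc)

      id_loss <- 0
      if (config$identity_weight > 0) {
        id_b <- net_forward(G_AB, b, train = TRUE)
        lid_b <- mean((id_b - b)^2)
        net_backward(G_AB, 2 * (id_b - b) / length(b) *
                       config$identity_weight * config$lambda_cycle)
        id_a <- net_forward(G_BA, a, train = TRUE)
        lid_a <- mean((id_a - a)^2)
        net_backward(G_BA, 2 * (id_a - a) / length(a) *
                       config$identity_weight * config$lambda_cycle)
        id_loss <- lid_a + lid_b
      }

      adam_step(G_AB, lr_e, config$beta1)
      adam_step(G_BA, lr_e, config$beta1)

      loss_G <- adv_g1 + adv_g2 +
        config$lambda_cycle * (cycA + cycB) +
        config$identity_weight * config$lambda_cycle * id_loss

      # --- discriminators (on detached fakes, optionally from the buffer) ---
      rB <- buf_push(bufB, fake_b, config$buffer_size)
      bufB <- rB$buf; fb_d <- rB$img
      rA <- buf_push(bufA, fake_a, config$buffer_size)
      bufA <- rA$buf; fa_d <- rA$img

      zero_grads(D_B)
      sc_rb <- net_forward(D_B, b, train = TRUE)
      net_backward(D_B, adv_grad_d_real(sc_rb))
      sc_fb2 <- net_forward(D_B, fb_d, train = TRUE)
      net_backward(D_B, adv_grad_d_fake(sc_fb2))
      loss_DB <- mean((sc_rb - 1)^2) + mean(sc_fb2^2)
      adam_step(D_B, lr_e, config$beta1)

      zero_grads(D_A)
      sc_ra <- net_forward(D_A, a, train = TRUE)
      net_backward(D_A, adv_grad_d_real(sc_ra))
      sc_fa2 <- net_forward(D_A, fa_d, train = TRUE)
      net_backward(D_A, adv_grad_d_fake(sc_fa2))
      loss_DA <- mean((sc_ra - 1)^2) + mean(sc_fa2^2)
      adam_step(D_A, lr_e, config$beta1)

      finite_or_abort(loss_G, loss_DA, loss_DB, epoch = epoch, step = s)
      acc <- acc + c(adv_g1 + adv_g2, loss_DA + loss_DB, cycA, cycB,
                     loss_G, loss_DA + loss_DB)
    }
    acc <- acc / n_steps

    val <- NA_real_
    if (!is.null(valA) && !is.null(valB)) {
      val <- validate_cycle(G_AB, G_BA, valA, valB, cyc_mode,
                            config$w_bg, config$w_fg)
    }
    metric <- if (!is.null(eval_fn)) eval_fn(G_AB, G_BA) else val

    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, adv_G = acc[1], adv_D = acc[2], cycle_A = acc[3],
      cycle_B = acc[4], total_G = acc[5], total_D = acc[6],
      val_loss = val, val_metric = metric,
      elapsed_s = proc.time()[["elapsed"]] - t0
    )
    if (verbose) {
      message(sprintf("epoch %3d  G %.4f  D %.4f  cycle %.4f/%.4f  val %s",
                      epoch, acc[5], acc[6], acc[3], acc[4],
                      ifelse(is.na(metric), "-", signif(metric, 4))))
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(G_AB, file.path(checkpoint_dir, sprintf("G_AB_epoch%03d.rds", epoch)))
      save_checkpoint(G_BA, file.path(checkpoint_dir, sprintf("G_BA_epoch%03d.rds", epoch)))
    }

    stopper <- if (!is.null(eval_fn)) metric else val
    if (is.finite(config$early_stop_patience) && !is.na(stopper)) {
      better <- if (!is.null(eval_fn) && eval_higher_better) {
        is.na(best_val) || stopper > best_val
      } else {
        is.na(best_val) || stopper < best_val
      }
      if (better) {
        best_val <- stopper; best_epoch <- epoch
      } else if (epoch - best_epoch >= config$early_stop_patience) {
        if (verbose) message("early stop at epoch ", epoch,
                             " (best epoch ", best_epoch, ")")
        break
      }
    }
  }

  history <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null, TRUE)])
  structure(list(G_AB = G_AB, G_BA = G_BA, D_A = D_A, D_B = D_B,
                 history = history, config = config),
            class = "tg_cyclegan")
}

validate_cycle <- function(G_AB, G_BA, valA, valB, cyc_mode, w_bg, w_fg) {
  lossA <- vapply(valA$patches, function(a) {
    rec <- net_forward(G_BA, net_forward(G_AB, a))
    cycle_loss(a, rec, cyc_mode, w_bg, w_fg)
  }, numeric(1))
  lossB <- vapply(valB$patches, function(b) {
    rec <- net_forward(G_AB, net_forward(G_BA, b))
    cycle_loss(b, rec, cyc_mode, w_bg, w_fg)
  }, numeric(1))
  mean(c(lossA, lossB))
}

#' @export
print.tg_cyclegan <- function(x, ...) {
  cat("<tg_cyclegan> trained ", nrow(x$history), " epochs; final G loss ",
      signif(tail(x$history$total_G, 1), 4), ", D loss ",
      signif(tail(x$history$total_D, 1), 4), "\n", sep = "")
  invisible(x)
}

# ---- Paired (supervised UNet) training ------------------------------------

#' Train the paired translation baseline
#'
#' Supervised regression of domain-B patches from spatially registered
#' domain-A patches with a UNet, using the same optimizer settings as the
#' unpaired trainer and an MSE (or Otsu-weighted MSE) loss.
#'
#' @param config A [train_config()].
#' @param setA,setB Registered patch sets: `setB$patches[[i]]` is the
#'   target for `setA$patches[[i]]`.
#' @param dims 2 or 3.
#' @param depth,base_filters UNet hyperparameters.
#' @param valA,valB Optional registered validation pairs.
#' @param eval_fn Optional `function(model) -> scalar` recorded per epoch.
#' @param eval_higher_better Direction of `eval_fn` for early stopping.
#' @param checkpoint_dir Optional per-epoch checkpoint directory.
#' @param verbose Print one line per epoch.
#' @return List of class `tg_paired`: `model`, `history`, `config`.
#' @export
train_paired <- function(config, setA, setB, dims = 2L, depth = 4L,
                         base_filters = 64L, valA = NULL, valB = NULL,
                         eval_fn = NULL, eval_higher_better = TRUE,
                         checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "tg_train_config"))
  check_patch_compat(setA, setB)
  if (length(setA$patches) != length(setB$patches)) {
    stop("paired training needs equally many A and B patches")
  }
  set.seed(config$seed)
  model <- build_unet(dims, 1L, 1L, depth, base_filters)
  n <- length(setA$patches)
  maskB <- if (config$use_otsu_loss) {
    lapply(setB$patches, function(p) suppressWarnings(otsu_mask(p)))
  } else NULL

  hist_rows <- vector("list", config$epochs)
  best_val <- NA_real_; best_epoch <- 0L
  t0 <- proc.time()[["elapsed"]]
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    lr_e <- epoch_lr(config, epoch)
    tot <- 0
    for (s in seq_len(n)) {
      a <- setA$patches[[ord[s]]]
      b <- setB$patches[[ord[s]]]
      zero_grads(model)
      pred <- net_forward(model, a, train = TRUE)
      if (config$use_otsu_loss) {
        loss <- weighted_mse(pred, b, maskB[[ord[s]]], config$w_bg, config$w_fg)
        g <- weighted_mse_grad(pred, b, maskB[[ord[s]]], config$w_bg, config$w_fg)
      } else {
        loss <- mean((pred - b)^2)
        g <- 2 * (pred - b) / length(b)
      }
      finite_or_abort(loss, epoch = epoch, step = s)
      net_backward(model, g)
      adam_step(model, lr_e, config$beta1)
      tot <- tot + loss
    }
    val <- NA_real_
    if (!is.null(valA) && !is.null(valB)) {
      val <- mean(vapply(seq_along(valA$patches), function(i) {
        mean((net_forward(model, valA$patches[[i]]) - valB$patches[[i]])^2)
      }, numeric(1)))
    }
    metric <- if (!is.null(eval_fn)) eval_fn(model) else val
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, train_loss = tot / n, val_loss = val,
      val_metric = metric, elapsed_s = proc.time()[["elapsed"]] - t0
    )
    if (verbose) {
      message(sprintf("epoch %3d  loss %.5f  val %s", epoch, tot / n,
                      ifelse(is.na(metric), "-", signif(metric, 4))))
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(model, file.path(checkpoint_dir, sprintf("unet_epoch%03d.rds", epoch)))
    }
    stopper <- metric
    if (is.finite(config$early_stop_patience) && !is.na(stopper)) {
      better <- if (!is.null(eval_fn) && eval_higher_better) {
        is.na(best_val) || stopper > best_val
      } else {
        is.na(best_val) || stopper < best_val
      }
      if (better) {
        best_val <- stopper; best_epoch <- epoch
      } else if (epoch - best_epoch >= config$early_stop_patience) {
        break
      }
    }
  }
  history <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null, TRUE)])
  structure(list(model = model, history = history, config = config),
            class = "tg_paired")
}
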