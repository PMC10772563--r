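#' Build a beta-variational autoencoder for beat templates
#'
#' The encoder is three affine+ReLU layers followed by two affine heads
#' producing the posterior mean and log-variance of a 16-dimensional Gaussian
#' latent; the decoder mirrors the encoder sizes and ends in a linear output
#' layer of the input dimension. Training minimises
#' `MSE + beta * KL(q(z|x) || N(0, I))`.
#'
#' @param input_dim Length of the (concatenated-lead) template vector.
#' @param hidden Exactly three encoder layer widths.
#' @param latent_dim Latent dimensionality (16).
#' @param beta KL weight (>= 0); 1 is the plain VAE. Together with the KL
#'   warm-up in [train_vae()] and enough epochs, the default keeps the
#'   aggregate posterior close to the standard-normal prior (per-dimension
#'   means near 0, aggregate sd near 1) at high reconstruction quality.
#' @param seed Integer seed for the weight initialisation.
#' @return Object of class `ecg_vae`.
#' @export
build_vae <- function(input_dim, hidden = c(512, 256, 128), latent_dim = 16L,
                      beta = 1, seed = 1L) {
  if (length(hidden) != 3L)
    stop("hidden must give exactly 3 encoder layer sizes", call. = FALSE)
  stopifnot(input_dim > latent_dim, beta >= 0)
  set.seed(seed)
  he <- function(n_in, n_out, scale = 2)
    matrix(rnorm(n_in * n_out, 0, sqrt(scale / n_in)), n_in, n_out)
  dims <- c(input_dim, hidden)
  par <- list()
  for (i in 1:3) {
    par[[paste0("W_e", i)]] <- he(dims[i], dims[i + 1])
    par[[paste0("b_e", i)]] <- numeric(dims[i + 1])
  }
  par$W_mu <- he(hidden[3], latent_dim, 1); par$b_mu <- numeric(latent_dim)
  par$W_lv <- he(hidden[3], latent_dim, 1); par$b_lv <- numeric(latent_dim)
  ddims <- c(latent_dim, rev(hidden))
  for (i in 1:3) {
    par[[paste0("W_d", i)]] <- he(ddims[i], ddims[i + 1])
    par[[paste0("b_d", i)]] <- numeric(ddims[i + 1])
  }
  par$W_o <- he(rev(hidden)[3], input_dim, 1); par$b_o <- numeric(input_dim)
  structure(list(input_dim = input_dim, hidden = hidden,
                 latent_dim = as.integer(latent_dim), beta = beta,
                 par = par, trained = FALSE, mode = NULL,
                 history = tibble(epoch = integer(), train_loss = double(),
                                  recon = double(), kl = double(),
                                  val_loss = double()),
                 seed = seed),
            class = "ecg_vae")
}

#' @export
print.ecg_vae <- function(x, ...) {
  np <- sum(vapply(x$par, length, integer(1)))
  cat(sprintf(
    "<ecg_vae> %d -> (%s) -> %d latent, beta = %g, %s, %d parameters\n",
    x$input_dim, paste(x$hidden, collapse = ", "), x$latent_dim, x$beta,
    if (x$trained) paste0("trained (", x$mode %||% "?", ")") else "untrained",
    np))
  invisible(x)
}

relu <- function(M) {
  M[M < 0] <- 0
  M
}

addb <- function(M, b) t(t(M) + b)

vae_forward <- function(par, X, E = NULL) {
  H1 <- relu(addb(X %*% par$W_e1, par$b_e1))
  H2 <- relu(addb(H1 %*% par$W_e2, par$b_e2))
  H3 <- relu(addb(H2 %*% par$W_e3, par$b_e3))
  MU <- addb(H3 %*% par$W_mu, par$b_mu)
  LV <- addb(H3 %*% par$W_lv, par$b_lv)
  LV <- pmin(pmax(LV, -10), 10)
  Z <- if (is.null(E)) MU else MU + exp(0.5 * LV) * E
  G1 <- relu(addb(Z %*% par$W_d1, par$b_d1))
  G2 <- relu(addb(G1 %*% par$W_d2, par$b_d2))
  G3 <- relu(addb(G2 %*% par$W_d3, par$b_d3))
  XH <- addb(G3 %*% par$W_o, par$b_o)
  list(H1 = H1, H2 = H2, H3 = H3, MU = MU, LV = LV, Z = Z,
       G1 = G1, G2 = G2, G3 = G3, XH = XH)
}

# loss and gradients for one minibatch (rows of X), with noise matrix E.
# The optimisation objective is the per-dimension-scaled negative ELBO
# (sum-squared-error reconstruction + beta * KL, divided by input_dim), so
# the KL gradient carries a 1/d factor relative to the mean-MSE recon term.
vae_grad <- function(par, X, E, beta) {
  f <- vae_forward(par, X, E)
  n <- nrow(X); d <- ncol(X)
  kw <- beta / d
  resid <- f$XH - X
  recon <- mean(resid^2)
  kl_rows <- -0.5 * rowSums(1 + f$LV - f$MU^2 - exp(f$LV))
  kl <- mean(kl_rows)
  g <- list()
  dXH <- 2 * resid / (n * d)
  g$W_o <- crossprod(f$G3, dXH); g$b_o <- colSums(dXH)
  dG3 <- (dXH %*% t(par$W_o)) * (f$G3 > 0)
  g$W_d3 <- crossprod(f$G2, dG3); g$b_d3 <- colSums(dG3)
  dG2 <- (dG3 %*% t(par$W_d3)) * (f$G2 > 0)
  g$W_d2 <- crossprod(f$G1, dG2); g$b_d2 <- colSums(dG2)
  dG1 <- (dG2 %*% t(par$W_d2)) * (f$G1 > 0)
  g$W_d1 <- crossprod(f$Z, dG1); g$b_d1 <- colSums(dG1)
  dZ <- dG1 %*% t(par$W_d1)
  dMU <- dZ + (kw / n) * f$MU
  dLV <- dZ * E * (0.5 * exp(0.5 * f$LV)) + (kw / n) * 0.5 * (exp(f$LV) - 1)
  g$W_mu <- crossprod(f$H3, dMU); g$b_mu <- colSums(dMU)
  g$W_lv <- crossprod(f$H3, dLV); g$b_lv <- colSums(dLV)
  dH3 <- (dMU %*% t(par$W_mu) + dLV %*% t(par$W_lv)) * (f$H3 > 0)
  g$W_e3 <- crossprod(f$H2, dH3); g$b_e3 <- colSums(dH3)
  dH2 <- (dH3 %*% t(par$W_e3)) * (f$H2 > 0)
  g$W_e2 <- crossprod(f$H1, dH2); g$b_e2 <- colSums(dH2)
  dH1 <- (dH2 %*% t(par$W_e2)) * (f$H1 > 0)
  g$W_e1 <- crossprod(X, dH1); g$b_e1 <- colSums(dH1)
  list(recon = recon, kl = kl, objective = recon + kw * kl, grads = g)
}

#' ELBO-derived training loss of a beta-VAE
#'
#' `recon` is the mean squared error over all samples and dimensions;
#' `kl = -0.5 * sum_i(1 + logvar_i - mu_i^2 - exp(logvar_i))` summed over
#' latent dimensions (and averaged over rows for matrix input);
#' `total = recon + beta * kl`.
#'
#' @param x Input vector, or matrix with one row per sample.
#' @param x_hat Reconstruction, same shape as `x`.
#' @param mu,logvar Posterior mean and log-variance (vector or matrix).
#' @param beta KL weight.
#' @return Object of class `vae_loss`: list with `recon`, `kl`, `beta`,
#'   `total`.
#' @export
vae_loss <- function(x, x_hat, mu, logvar, beta = 1) {
  x <- rbind(x); x_hat <- rbind(x_hat); mu <- rbind(mu); logvar <- rbind(logvar)
  if (!all(is.finite(x)) || !all(is.finite(x_hat)) ||
      !all(is.finite(mu)) || !all(is.finite(logvar)))
    stop("non-finite inputs to vae_loss", call. = FALSE)
  stopifnot(all(dim(x) == dim(x_hat)), all(dim(mu) == dim(logvar)))
  recon <- mean((x - x_hat)^2)
  kl <- mean(-0.5 * rowSums(1 + logvar - mu^2 - exp(logvar)))
  structure(list(recon = recon, kl = kl, beta = beta,
                 total = recon + beta * kl),
            class = "vae_loss")
}

#' @export
print.vae_loss <- function(x, ...) {
  cat(sprintf("<vae_loss> total %.6g = recon %.6g + %g * KL %.6g\n",
              x$total, x$recon, x$beta, x$kl))
  invisible(x)
}

#' Reparameterised Monte-Carlo sample from the latent posterior
#'
#' @param mu,logvar Posterior mean and log-variance (vectors or matrices).
#' @param seed Optional integer seed.
#' @return `z = mu + exp(logvar / 2) * eps` with `eps ~ N(0, 1)`.
#' @export
sample_latent <- function(mu, logvar, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eps <- if (is.matrix(mu)) matrix(rnorm(length(mu)), nrow(mu)) else
    rnorm(length(mu))
  mu + exp(0.5 * logvar) * eps
}

#' Train a beta-VAE by minibatch Adam
#'
#' Ten percent of the training rows (or an explicit validation index) are
#' held out; training stops early when the validation loss has not improved
#' for `patience` epochs, and the best-validation weights are restored.
#' `mode = "finetune"` continues from the current weights.
#'
#' @param model An [build_vae()] model.
#' @param x Numeric matrix, one template vector per row (values in `[0, 1]`).
#' @param epochs Maximum epochs; 0 returns the model unchanged.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param seed Integer seed controlling shuffling, noise and the validation
#'   split.
#' @param mode `"pretrain"` or `"finetune"`.
#' @param val_frac Fraction of rows used for validation.
#' @param val_rows Optional explicit validation row indices (e.g. all rows
#'   of the held-out patients).
#' @param patience Early-stopping patience in epochs.
#' @param warmup Epochs over which the KL weight is linearly annealed from 0
#'   to `beta` (KL warm-up avoids early posterior collapse); 0 disables.
#' @param verbose Print per-epoch losses?
#' @return The trained `ecg_vae` with its loss `history` updated.
#' @export
train_vae <- function(model, x, epochs = 100, batch_size = 128, lr = 1e-3,
                      seed = 1L, mode = c("pretrain", "finetune"),
                      val_frac = 0.1, val_rows = NULL, patience = 15,
                      warmup = 10, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "ecg_vae"), is.matrix(x))
  if (ncol(x) != model$input_dim)
    stop("template dimension ", ncol(x), " does not match model input ",
         model$input_dim, call. = FALSE)
  if (epochs == 0) return(model)
  set.seed(seed)
  n <- nrow(x)
  if (is.null(val_rows))
    val_rows <- sample.int(n, max(1L, round(val_frac * n)))
  tr_rows <- setdiff(seq_len(n), val_rows)
  Xtr <- x[tr_rows, , drop = FALSE]
  Xval <- x[val_rows, , drop = FALSE]
  par <- model$par
  m_st <- lapply(par, function(p) p * 0)
  v_st <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; epsad <- 1e-8; step <- 0
  best <- list(loss = Inf, par = par, epoch = 0L)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    beta_ep <- if (warmup > 0) model$beta * min(1, ep / warmup) else model$beta
    ord <- sample.int(nrow(Xtr))
    nb <- ceiling(nrow(Xtr) / batch_size)
    ep_recon <- ep_kl <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * batch_size + 1):min(bi * batch_size, nrow(Xtr))]
      Xb <- Xtr[idx, , drop = FALSE]
      E <- matrix(rnorm(length(idx) * model$latent_dim), length(idx))
      gr <- vae_grad(par, Xb, E, beta_ep)
      step <- step + 1
      for (nm in names(par)) {
        m_st[[nm]] <- b1 * m_st[[nm]] + (1 - b1) * gr$grads[[nm]]
        v_st[[nm]] <- b2 * v_st[[nm]] + (1 - b2) * gr$grads[[nm]]^2
        mh <- m_st[[nm]] / (1 - b1^step)
        vh <- v_st[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + epsad)
      }
      w <- length(idx) / nrow(Xtr)
      ep_recon <- ep_recon + w * gr$recon
      ep_kl <- ep_kl + w * gr$kl
    }
    Ev <- matrix(rnorm(nrow(Xval) * model$latent_dim), nrow(Xval))
    fv <- vae_forward(par, Xval, Ev)
    vl <- vae_loss(Xval, fv$XH, fv$MU, fv$LV, model$beta)
    kw <- model$beta / ncol(x)
    val_obj <- vl$recon + kw * vl$kl
    hist[[ep]] <- tibble(epoch = ep, train_loss = ep_recon + kw * ep_kl,
                         recon = ep_recon, kl = ep_kl, val_loss = val_obj)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                      hist[[ep]]$train_loss, vl$total))
    if (val_obj < best$loss - 1e-6) {
      best <- list(loss = val_obj, par = par, epoch = ep)
    } else if (ep - best$epoch >= patience) break
  }
  model$par <- best$par
  model$trained <- TRUE
  model$mode <- mode
  model$history <- bind_rows(model$history, bind_rows(hist))
  model
}

#' Encode templates into the latent posterior
#'
#' Deterministic given the model parameters; downstream features use the
#' posterior mean, never a Monte-Carlo sample.
#'
#' @param model A trained `ecg_vae`.
#' @param x Template vector, matrix (rows = templates), [beat_template()],
#'   or template table with a `template` list-column.
#' @return List with matrices `mu` and `logvar` (`n x 16`).
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "ecg_vae"))
  X <- if (inherits(x, "beat_template")) rbind(template_vector(x))
  else if (is.data.frame(x)) template_matrix(x)
  else rbind(x)
  if (ncol(X) != model$input_dim)
    stop("input dimension mismatch: got ", ncol(X), ", model expects ",
         model$input_dim, call. = FALSE)
  f <- vae_forward(model$par, X, E = NULL)
  list(mu = f$MU, logvar = f$LV)
}

#' Decode latent vectors into template reconstructions
#'
#' @param model A trained `ecg_vae`.
#' @param z Latent vector or matrix (rows = latent codes).
#' @return Matrix of reconstructed template vectors, one row per code.
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "ecg_vae"))
  Z <- rbind(z)
  if (ncol(Z) != model$latent_dim)
    stop("latent dimension mismatch", call. = FALSE)
  par <- model$par
  G1 <- relu(addb(Z %*% par$W_d1, par$b_d1))
  G2 <- relu(addb(G1 %*% par$W_d2, par$b_d2))
  G3 <- relu(addb(G2 %*% par$W_d3, par$b_d3))
  addb(G3 %*% par$W_o, par$b_o)
}

#' Latent codes (posterior means) for a template table
#'
#' @param model A trained `ecg_vae`.
#' @param templates Tibble `(patient_id, day, template)`.
#' @return Tibble `(patient_id, day, AE0..AE15)`.
#' @export
encode_templates <- function(model, templates) {
  enc <- encode(model, templates)
  mu <- enc$mu
  colnames(mu) <- paste0("AE", seq_len(ncol(mu)) - 1L)
  bind_cols(templates[, c("patient_id", "day")], as_tibble(mu))
}

#' Reconstruction quality metrics after min-max normalisation
#'
#' Both signals are min-max normalised before computing Pearson's r, RMSE,
#' the percentage root-mean-square difference
#' `PRD = 100 * sqrt(sum((x - x_hat)^2) / sum(x^2))` and the dynamic time
#' warping cost (absolute local distance, unit steps). If a signal is
#' constant after normalisation, `r` is reported as `NA`.
#'
#' @param x,x_hat Equal-length numeric vectors.
#' @return One-row tibble with `r`, `rmse`, `prd`, `dtw`.
#' @export
reconstruction_metrics <- function(x, x_hat) {
  stopifnot(length(x) == length(x_hat))
  mm <- function(v) {
    rng <- range(v)
    if (diff(rng) < 1e-12) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  }
  xn <- mm(x); xhn <- mm(x_hat)
  r <- if (stats::sd(xn) < 1e-12 || stats::sd(xhn) < 1e-12) NA_real_
  else cor(xn, xhn)
  rmse <- sqrt(mean((xn - xhn)^2))
  prd <- 100 * sqrt(sum((xn - xhn)^2) / sum(xn^2))
  tibble(r = r, rmse = rmse, prd = prd, dtw = dtw_distance(xn, xhn))
}

#' Per-template reconstruction metrics of a trained model
#'
#' @param model A trained `ecg_vae`.
#' @param X Template matrix (rows = templates).
#' @return Tibble of [reconstruction_metrics()] rows, one per template.
#' @export
evaluate_reconstruction <- function(model, X) {
  XH <- decode(model, encode(model, X)$mu)
  bind_rows(lapply(seq_len(nrow(X)), function(i)
    reconstruction_metrics(X[i, ], XH[i, ])))
}

#' Dynamic time warping distance between two waveforms
#'
#' Classical DTW with absolute-difference local cost and unit step pattern
#' (insertion, deletion, match), returning the accumulated cost of the
#' optimal alignment path.
#'
#' @param a,b Numeric vectors.
#' @return Non-negative scalar cost.
#' @export
dtw_distance <- function(a, b) {
  dtw_distance_cpp(as.numeric(a), as.numeric(b))
}

#' Save / load a VAE checkpoint
#'
#' The checkpoint is a directory holding `architecture.json` (dimensions,
#' beta, seed, training state) and `weights.rds` (the parameter list).
#'
#' @param model An `ecg_vae`.
#' @param path Checkpoint directory.
#' @return `save_vae()` the path, invisibly; `load_vae()` the model.
#' @export
save_vae <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arch <- list(input_dim = model$input_dim, hidden = model$hidden,
               latent_dim = model$latent_dim, beta = model$beta,
               trained = model$trained, mode = model$mode, seed = model$seed)
  jsonlite::write_json(arch, file.path(path, "architecture.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(model$par, file.path(path, "weights.rds"))
  utils::write.csv(model$history, file.path(path, "history.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  arch <- jsonlite::read_json(file.path(path, "architecture.json"),
                              simplifyVector = TRUE)
  model <- build_vae(arch$input_dim, arch$hidden, arch$latent_dim, arch$beta,
                     seed = arch$seed %||% 1L)
  model$par <- readRDS(file.path(path, "weights.rds"))
  model$trained <- isTRUE(arch$trained)
  model$mode <- arch$mode
  hp <- file.path(path, "history.csv")
  if (file.exists(hp)) model$history <- as_tibble(utils::read.csv(hp))
  model
}

#' @export
tidy.ecg_vae <- function(x, ...) x$history

#' @export
glance.ecg_vae <- function(x, ...) {
  np <- sum(vapply(x$par, length, integer(1)))
  last <- if (nrow(x$history)) utils::tail(x$history, 1) else
    tibble(train_loss = NA_real_, val_loss = NA_real_)
  tibble(input_dim = x$input_dim, latent_dim = x$latent_dim, beta = x$beta,
         n_parameters = np, trained = x$trained,
         epochs = nrow(x$history), train_loss = last$train_loss,
         val_loss = last$val_loss)
}
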