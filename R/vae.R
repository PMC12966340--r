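#' Variational autoencoder for commonness feature vectors
#'
#' A small fully-connected VAE trained on the standardized species-feature
#' matrix and used as an anomaly scorer: species whose feature vectors the
#' trained model reconstructs poorly (low reconstruction log-probability)
#' deviate from the dominant structure of the species pool and are
#' candidates for the rare class.
#'
#' Architecture: two tanh hidden layers in the encoder, mapping to the mean
#' and log-variance of a diagonal-Gaussian posterior `q(z|x)`; the decoder
#' mirrors the encoder (hidden widths reversed) and outputs a linear
#' reconstruction mean. Training minimises mean squared reconstruction error
#' plus the KL divergence of `q(z|x)` from the standard normal prior, by
#' full-batch Adam with a fixed epoch budget. The hidden widths are
#' found by a growing search and the latent dimensionality by a sweep; see
#' [train_vae()].
#'
#' @name vae_model
NULL

vae_init <- function(d_in, widths, d_lat) {
  sd0 <- 0.1
  rmat <- function(r, c) matrix(stats::rnorm(r * c, sd = sd0), r, c)
  list(
    d_in = d_in, widths = widths, d_lat = d_lat,
    W1 = rmat(d_in, widths[1]), b1 = numeric(widths[1]),
    W2 = rmat(widths[1], widths[2]), b2 = numeric(widths[2]),
    Wm = rmat(widths[2], d_lat), bm = numeric(d_lat),
    Wv = rmat(widths[2], d_lat), bv = numeric(d_lat),
    U1 = rmat(d_lat, widths[2]), c1 = numeric(widths[2]),
    U2 = rmat(widths[2], widths[1]), c2 = numeric(widths[1]),
    U3 = rmat(widths[1], d_in), c3 = numeric(d_in)
  )
}

vae_encode <- function(m, X) {
  H1 <- tanh(sweep(X %*% m$W1, 2, m$b1, "+"))
  H2 <- tanh(sweep(H1 %*% m$W2, 2, m$b2, "+"))
  list(H1 = H1, H2 = H2,
       Mu = sweep(H2 %*% m$Wm, 2, m$bm, "+"),
       Lv = sweep(H2 %*% m$Wv, 2, m$bv, "+"))
}

vae_decode <- function(m, Z) {
  G1 <- tanh(sweep(Z %*% m$U1, 2, m$c1, "+"))
  G2 <- tanh(sweep(G1 %*% m$U2, 2, m$c2, "+"))
  list(G1 = G1, G2 = G2, Xhat = sweep(G2 %*% m$U3, 2, m$c3, "+"))
}

vae_par_names <- function() {
  c("W1", "b1", "W2", "b2", "Wm", "bm", "Wv", "bv",
    "U1", "c1", "U2", "c2", "U3", "c3")
}

# One full-batch Adam step; returns updated model and the loss.
vae_step <- function(m, X, lr, opt) {
  n <- nrow(X)
  enc <- vae_encode(m, X)
  Eps <- matrix(stats::rnorm(n * m$d_lat), n, m$d_lat)
  Sig <- exp(0.5 * enc$Lv)
  Z <- enc$Mu + Sig * Eps
  dec <- vae_decode(m, Z)

  R <- dec$Xhat - X
  recon <- 0.5 * sum(R^2) / n
  kl <- 0.5 * sum(exp(enc$Lv) + enc$Mu^2 - 1 - enc$Lv) / n
  loss <- recon + kl

  dXhat <- R / n
  dU3 <- crossprod(dec$G2, dXhat); dc3 <- colSums(dXhat)
  dG2 <- (dXhat %*% t(m$U3)) * (1 - dec$G2^2)
  dU2 <- crossprod(dec$G1, dG2); dc2 <- colSums(dG2)
  dG1 <- (dG2 %*% t(m$U2)) * (1 - dec$G1^2)
  dU1 <- crossprod(Z, dG1); dc1 <- colSums(dG1)
  dZ <- dG1 %*% t(m$U1)

  dMu <- dZ + enc$Mu / n
  dLv <- dZ * Eps * 0.5 * Sig + 0.5 * (exp(enc$Lv) - 1) / n
  dWm <- crossprod(enc$H2, dMu); dbm <- colSums(dMu)
  dWv <- crossprod(enc$H2, dLv); dbv <- colSums(dLv)
  dH2 <- (dMu %*% t(m$Wm) + dLv %*% t(m$Wv)) * (1 - enc$H2^2)
  dW2 <- crossprod(enc$H1, dH2); db2 <- colSums(dH2)
  dH1 <- (dH2 %*% t(m$W2)) * (1 - enc$H1^2)
  dW1 <- crossprod(X, dH1); db1 <- colSums(dH1)

  grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                Wm = dWm, bm = dbm, Wv = dWv, bv = dbv,
                U1 = dU1, c1 = dc1, U2 = dU2, c2 = dc2,
                U3 = dU3, c3 = dc3)
  # Adam update (beta1 = 0.9, beta2 = 0.999)
  opt$t <- opt$t + 1L
  b1c <- 1 - 0.9^opt$t
  b2c <- 1 - 0.999^opt$t
  for (p in vae_par_names()) {
    g <- grads[[p]]
    opt$m[[p]] <- 0.9 * opt$m[[p]] + 0.1 * g
    opt$v[[p]] <- 0.999 * opt$v[[p]] + 0.001 * g^2
    m[[p]] <- m[[p]] - lr * (opt$m[[p]] / b1c) /
      (sqrt(opt$v[[p]] / b2c) + 1e-8)
  }
  list(model = m, loss = loss, recon = recon, kl = kl, opt = opt)
}

adam_init <- function(m) {
  zero <- lapply(vae_par_names(), function(p) m[[p]] * 0)
  names(zero) <- vae_par_names()
  list(t = 0L, m = zero, v = zero)
}

# Train one architecture for a fixed epoch budget; restarts with a halved
# learning rate (up to 3 times) if the loss goes non-finite.
vae_train_one <- function(X, widths, d_lat, epochs, lr, seed) {
  with_seed(seed, {
    for (attempt in 0:3) {
      m <- vae_init(ncol(X), widths, d_lat)
      opt <- adam_init(m)
      step_lr <- lr / 2^attempt
      ok <- TRUE
      trace <- numeric(epochs)
      for (e in seq_len(epochs)) {
        st <- vae_step(m, X, step_lr, opt)
        if (!is.finite(st$loss)) { ok <- FALSE; break }
        m <- st$model
        opt <- st$opt
        trace[e] <- st$loss
      }
      if (ok) {
        m$loss_trace <- trace
        m$lr_used <- step_lr
        return(m)
      }
    }
    stop("VAE training diverged after 3 learning-rate restarts", call. = FALSE)
  })
}

#' Train the VAE with architecture growth and latent-dimension sweep
#'
#' The growing search starts from two hidden layers of width
#' `cfg$vae$start_widths` and repeatedly trains candidate architectures with
#' one extra node in either hidden layer, accepting the candidate that most
#' improves the mean reconstruction log-probability on the training set;
#' growth stops when no candidate improves by more than `cfg$vae$grow_tol`
#' or both layers reach `cfg$vae$max_width`. Latent dimensionalities
#' `cfg$vae$latent_dims` (capped at the input dimension) are swept, and the
#' configuration with the highest mean reconstruction log-probability wins.
#' Deterministic given the seed. A warning is raised when fewer than ten
#' times as many rows as features are supplied, since anomaly-based rarity
#' scoring needs a species pool substantially larger than the feature
#' dimensionality.
#'
#' @param X standardized feature matrix (rows = species).
#' @param cfg a [study_config()]; `cfg$vae` holds the hyperparameters.
#' @param seed overrides `cfg$seed` when given.
#' @return the trained model (list of class `pc_vae`) with elements
#'   `widths`, `d_lat`, the weight matrices, `search_trace` (one row per
#'   candidate evaluated) and `score` (its training-set mean reconstruction
#'   log-probability).
#' @export
train_vae <- function(X, cfg, seed = NULL) {
  X <- as.matrix(X)
  opts <- cfg$vae
  seed <- seed %||% cfg$seed
  if (nrow(X) < 10 * ncol(X)) {
    warning(sprintf(paste0(
      "only %d species for %d features; anomaly-based rarity scoring is ",
      "unreliable below ~10 species per feature"), nrow(X), ncol(X)),
      call. = FALSE)
  }
  lat_dims <- opts$latent_dims[opts$latent_dims <= ncol(X)]
  trace <- list()
  best <- NULL
  cand_id <- 0L
  for (d_lat in lat_dims) {
    widths <- pmin(opts$start_widths, opts$max_width)
    cur <- vae_train_one(X, widths, d_lat, opts$epochs, opts$lr,
                         derive_seed(seed, 1000L * d_lat))
    cur_score <- vae_mean_logprob(cur, X, opts$search_samples,
                                  derive_seed(seed, 1L))
    repeat {
      cands <- list()
      if (widths[1] < opts$max_width) cands <- c(cands, list(widths + c(1L, 0L)))
      if (widths[2] < opts$max_width) cands <- c(cands, list(widths + c(0L, 1L)))
      if (length(cands) == 0) break
      cand_models <- lapply(cands, function(w) {
        cand_id <<- cand_id + 1L
        m <- vae_train_one(X, w, d_lat, opts$epochs, opts$lr,
                           derive_seed(seed, 1000L * d_lat + cand_id))
        s <- vae_mean_logprob(m, X, opts$search_samples, derive_seed(seed, 1L))
        trace[[length(trace) + 1L]] <<-
          data.frame(latent_dim = d_lat, width1 = w[1], width2 = w[2],
                     score = s)
        list(model = m, score = s, widths = w)
      })
      scores <- vapply(cand_models, `[[`, numeric(1), "score")
      j <- which.max(scores)
      if (scores[j] > cur_score + opts$grow_tol) {
        cur <- cand_models[[j]]$model
        cur_score <- scores[j]
        widths <- cand_models[[j]]$widths
      } else break
    }
    trace[[length(trace) + 1L]] <-
      data.frame(latent_dim = d_lat, width1 = widths[1], width2 = widths[2],
                 score = cur_score)
    if (is.null(best) || cur_score > best$score) {
      best <- list(model = cur, score = cur_score, widths = widths,
                   d_lat = d_lat)
    }
  }
  m <- best$model
  m$score <- best$score
  m$search_trace <- do.call(rbind, trace)
  m$training_seed <- seed
  class(m) <- "pc_vae"
  m
}

# Mean reconstruction log-probability over all rows (model-selection score).
vae_mean_logprob <- function(m, X, L, seed) {
  mean(vae_logprob(m, X, L, seed))
}

# Per-row reconstruction log-probability: mean over L posterior samples of
# log N(x; decoder(z), I).
vae_logprob <- function(m, X, L, seed) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  enc <- vae_encode(m, X)
  Sig <- exp(0.5 * enc$Lv)
  with_seed(seed, {
    acc <- numeric(n)
    for (l in seq_len(L)) {
      Eps <- matrix(stats::rnorm(n * m$d_lat), n, m$d_lat)
      dec <- vae_decode(m, enc$Mu + Sig * Eps)
      acc <- acc + (-0.5 * rowSums((X - dec$Xhat)^2) - d / 2 * log(2 * pi))
    }
    acc / L
  })
}

#' Reconstruction log-probability scores
#'
#' For each species vector, draws `L` samples from the encoder posterior
#' `q(z|x)` and averages the Gaussian (identity covariance) log-likelihood
#' of the input under the decoder reconstruction. Scores are comparable
#' only within one trained model; low scores flag anomalous species.
#'
#' @param m a trained `pc_vae`.
#' @param X the standardized feature matrix (same columns as training).
#' @param L Monte-Carlo posterior samples (default from training options or
#'   100).
#' @param seed integer seed for the posterior draws.
#' @return named numeric vector of per-species scores (nats).
#' @export
reconstruction_scores <- function(m, X, L = 100, seed = NULL) {
  seed <- seed %||% derive_seed(m$training_seed, 7L)
  s <- vae_logprob(m, X, L, seed)
  names(s) <- rownames(X)
  s
}

#' Quantile grouping of reconstruction scores
#'
#' Splits species into `C` groups at the `j/C` empirical quantiles
#' (linear-interpolation convention) of the score distribution, ascending:
#' group 1 holds the lowest (most anomalous) scores. Ties at a boundary go
#' to the lower group; if all scores are equal every species lands in group
#' 1 (logged as degenerate).
#'
#' @param scores numeric vector of reconstruction scores.
#' @param C number of groups, `2 <= C <= length(scores)`.
#' @return integer vector of group indices in `1..C`.
#' @export
quantile_groups <- function(scores, C) {
  n <- length(scores)
  if (C < 2) stop("C must be at least 2", call. = FALSE)
  if (C > n) stop("more groups than scores", call. = FALSE)
  breaks <- stats::quantile(scores, probs = seq_len(C - 1) / C,
                            names = FALSE, type = 7)
  g <- 1L + vapply(scores, function(s) sum(s > breaks), integer(1))
  if (all(g == g[1]) && stats::sd(scores) == 0) {
    pc_log("degenerate score distribution: all species in group 1")
    g <- rep(1L, n)
  }
  names(g) <- names(scores)
  g
}

#' @export
print.pc_vae <- function(x, ...) {
  cat(sprintf("VAE: hidden widths (%d, %d), latent dim %d, mean recon logprob %.3f\n",
              x$widths[1], x$widths[2], x$d_lat, x$score))
  invisible(x)
}
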