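#' Configuration for the recurrent glucose predictor
#'
#' The model is a single LSTM layer followed by a dense hidden layer and a
#' categorical output head: a softmax over a fixed grid of 100 candidate
#' glucose values, trained by minimizing the negative log-likelihood of the
#' observed next-step glucose (nearest grid cell) with Adam. The point
#' estimate is the distribution expectation; percentile bands come from the
#' discrete distribution.
#'
#' @param lstm_units Hidden size of the LSTM layer.
#' @param dense_units Size of the dense hidden layer.
#' @param glucose_grid Strictly increasing grid of 100 candidate glucose
#'   values (mg/dL); default uniform on 40-400.
#' @param sequence_length Number of 15-min frames per input window.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param feedback_max Final probability of the scheduled-sampling
#'   feedback: over the epochs, the chance that a frame's glucose input is
#'   replaced by the model's own previous prediction ramps linearly from 0
#'   to this value.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return A list of class `cgp_config`.
#' @export
cgp_config <- function(lstm_units = 16, dense_units = 32,
                       glucose_grid = seq(40, 400, length.out = 100),
                       sequence_length = 16, learning_rate = 0.02,
                       batch_size = 32, epochs = 15, feedback_max = 1,
                       seed = 1L) {
  stopifnot(lstm_units >= 1, dense_units >= 1, sequence_length >= 2,
            learning_rate > 0, batch_size >= 1, epochs >= 1,
            feedback_max >= 0, feedback_max <= 1)
  if (length(glucose_grid) != 100 || any(diff(glucose_grid) <= 0)) {
    stop("glucose_grid must be strictly increasing with 100 points")
  }
  structure(
    list(lstm_units = as.integer(lstm_units),
         dense_units = as.integer(dense_units),
         glucose_grid = glucose_grid,
         sequence_length = as.integer(sequence_length),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), feedback_max = feedback_max,
         seed = as.integer(seed)),
    class = "cgp_config"
  )
}

# feature layout: name, standardization center/scale, ablation group
cgp_features <- data.frame(
  name = c("glucose", "hr", "exercise_min", "sin_t", "cos_t", "kcal",
           "carb_g", "sugar_g", "protein_g", "fat_g", "satfat_g", "fiber_g"),
  center = c(120, 70, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
  scale = c(60, 15, 15, 1, 1, 600, 60, 30, 30, 30, 15, 10),
  group = c("glucose", "heart_rate", "activity", "time_of_day",
            "time_of_day", rep("nutrients", 7)),
  stringsAsFactors = FALSE
)

cgp_feature_groups <- function() {
  split(seq_len(nrow(cgp_features)), cgp_features$group)
}

#' Per-step feature frames for a participant
#'
#' Builds the model's input representation on the 15-min CGM grid for the
#' requested days: interpolated glucose, mean heart rate in the step,
#' exercise minutes overlapping the step, time of day as a (sin, cos)
#' pair, and the nutrient totals of foods logged in the step. Values are
#' unscaled; standardization happens inside the model.
#'
#' @param record A [participant_record()].
#' @param days Integer vector of program days.
#' @return Data frame with one row per 15-min step: `day`, `time_min`, and
#'   the feature columns.
#' @export
build_frames <- function(record, days) {
  step <- record$glucose$step_min
  per_day <- 1440 %/% step
  out <- lapply(sort(unique(days)), function(d) {
    idx <- trace_window(record$glucose, d)
    t0 <- (d - 1) * 1440
    times <- t0 + (seq_len(per_day) - 1) * step
    g <- record$glucose$values[idx]
    if (anyNA(g)) {
      known <- which(!is.na(g))
      if (length(known) >= 2) {
        g <- stats::approx(known, g[known], xout = seq_along(g),
                           rule = 2)$y
      } else if (length(known) == 1) {
        g[] <- g[known]
      }
    }
    hr_min <- record$heart_rate[(t0 + 1):(t0 + 1440)]
    hr <- colMeans(matrix(hr_min, nrow = step), na.rm = TRUE)
    if (anyNA(hr) || any(is.nan(hr))) {
      bad <- is.na(hr) | is.nan(hr)
      hr[bad] <- mean(hr[!bad])
    }
    ex <- numeric(per_day)
    acts <- record$activities[record$activities$day == d, , drop = FALSE]
    for (i in seq_len(nrow(acts))) {
      a0 <- acts$time_min[i]
      a1 <- a0 + acts$minutes[i]
      ov <- pmax(0, pmin(times + step, a1) - pmax(times, a0))
      ex <- ex + ov
    }
    nut <- matrix(0, per_day, 7,
                  dimnames = list(NULL, nutrient_cols))
    mls <- record$meals[record$meals$day == d, , drop = FALSE]
    for (i in seq_len(nrow(mls))) {
      slot <- floor((mls$time_min[i] - t0) / step) + 1
      if (slot >= 1 && slot <= per_day) {
        nut[slot, ] <- nut[slot, ] +
          unlist(mls[i, nutrient_cols])
      }
    }
    tod <- times %% 1440
    data.frame(day = d, time_min = times, glucose = g, hr = hr,
               exercise_min = ex, sin_t = sin(2 * pi * tod / 1440),
               cos_t = cos(2 * pi * tod / 1440), nut)
  })
  do.call(rbind, out)
}

# scale a frame data.frame into the model's feature matrix
scale_frames <- function(frames) {
  m <- as.matrix(frames[, cgp_features$name])
  sweep(sweep(m, 2, cgp_features$center), 2, cgp_features$scale, "/")
}

# a complete day has at least `min_hours` of both CGM and HR capture and
# at least two logged meals
complete_days <- function(record, min_hours = 12, min_meals = 2) {
  step <- record$glucose$step_min
  slots_needed <- min_hours * 60 / step
  days <- seq_len(record$program_days)
  ok <- vapply(days, function(d) {
    g_ok <- sum(!is.na(record$glucose$values[trace_window(record$glucose,
                                                          d)])) >=
      slots_needed
    t0 <- (d - 1) * 1440
    hr_ok <- sum(!is.na(record$heart_rate[(t0 + 1):(t0 + 1440)])) >=
      min_hours * 60
    meals_ok <- sum(record$meals$day == d) >= min_meals
    g_ok && hr_ok && meals_ok
  }, FALSE)
  days[ok]
}

#' Training sequences from a participant record
#'
#' Slides a window of `sequence_length` frames over each complete day
#' (at least 12 h of both CGM and HR capture, and logged meals); the
#' target of each window is the next step's glucose. Windows never cross a
#' day boundary, so one complete day of 96 steps yields
#' `96 - sequence_length` sequences.
#'
#' @param record A [participant_record()].
#' @param cfg A [cgp_config()].
#' @param days Days to consider (default: all program days).
#' @param min_complete_days Minimum number of complete days required
#'   (default 5); fewer raises an insufficient-data error.
#' @return A list of class `cgp_sequences`: the input tensor `x`
#'   (n, sequence_length, features), raw targets `y`, target grid indices
#'   `y_idx`, per-sequence `day` and target position `pos`, and the
#'   per-day frame matrices used for scheduled sampling.
#' @export
build_sequences <- function(record, cfg, days = seq_len(record$program_days),
                            min_complete_days = 5) {
  ok_days <- intersect(complete_days(record), days)
  if (length(ok_days) < min_complete_days) {
    stop("insufficient data: ", length(ok_days),
         " complete days, need ", min_complete_days)
  }
  L <- cfg$sequence_length
  day_data <- list()
  for (d in ok_days) {
    fr <- build_frames(record, d)
    M <- scale_frames(fr)
    g <- fr$glucose
    P <- seq(L + 1, nrow(M))
    if (!length(P)) next
    day_data[[as.character(d)]] <- list(day = d, M = M, g = g, P = P)
  }
  tensors <- sequences_tensor(day_data, L, cfg$glucose_grid)
  structure(
    c(tensors,
      list(days = day_data, sequence_length = L, grid = cfg$glucose_grid,
           feature_names = cgp_features$name)),
    class = "cgp_sequences"
  )
}

# assemble the (n, L, D) tensor from per-day frame matrices; `override_g`
# optionally supplies a per-day replacement for the scaled glucose channel
sequences_tensor <- function(day_data, L, grid, override_g = NULL) {
  xs <- list()
  ys <- list()
  day_id <- list()
  pos <- list()
  D <- nrow(cgp_features)
  for (nm in names(day_data)) {
    dd <- day_data[[nm]]
    M <- dd$M
    if (!is.null(override_g) && !is.null(override_g[[nm]])) {
      M[, 1] <- override_g[[nm]]
    }
    n_day <- length(dd$P)
    idx <- outer(dd$P - L - 1, seq_len(L), "+")
    xs[[nm]] <- array(M[as.vector(idx), ], c(n_day, L, D))
    ys[[nm]] <- dd$g[dd$P]
    day_id[[nm]] <- rep(dd$day, n_day)
    pos[[nm]] <- dd$P
  }
  n_per <- vapply(xs, function(a) dim(a)[1], 0L)
  x <- array(0, c(sum(n_per), L, D))
  at <- 0L
  for (a in xs) {
    x[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  y <- unlist(ys, use.names = FALSE)
  list(x = x, y = y,
       y_idx = vapply(y, function(v) which.min(abs(grid - v)), 0L),
       day = unlist(day_id, use.names = FALSE),
       pos = unlist(pos, use.names = FALSE), n = length(y))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(D, H, U, K) {
  r <- function(n, m, fan) matrix(stats::runif(n * m, -1, 1) / sqrt(fan),
                                  n, m)
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias opens the memory path early
  list(Wx = r(D, 4 * H, D), Wh = r(H, 4 * H, H), b = b,
       W1 = r(H, U, H), b1 = numeric(U),
       W2 = r(U, K, U), b2 = numeric(K))
}

lstm_forward <- function(par, x, keep_cache = FALSE) {
  dims <- dim(x)
  N <- dims[1]; L <- dims[2]; D <- dims[3]
  H <- nrow(par$Wh)
  h <- matrix(0, N, H)
  cc <- matrix(0, N, H)
  ii <- seq_len(H); fi <- H + ii; gi <- 2 * H + ii; oi <- 3 * H + ii
  cache <- if (keep_cache) vector("list", L) else NULL
  for (t in seq_len(L)) {
    Xt <- matrix(x[, t, ], N, D)
    Z <- Xt %*% par$Wx + h %*% par$Wh
    Z <- sweep(Z, 2, par$b, "+")
    i <- sigmoid(Z[, ii, drop = FALSE])
    f <- sigmoid(Z[, fi, drop = FALSE])
    g <- tanh(Z[, gi, drop = FALSE])
    o <- sigmoid(Z[, oi, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    if (keep_cache) {
      cache[[t]] <- list(Xt = Xt, h_prev = h, c_prev = cc, i = i, f = f,
                         g = g, o = o, tc = tc)
    }
    h <- o * tc
    cc <- c_new
  }
  A1 <- tanh(sweep(h %*% par$W1, 2, par$b1, "+"))
  logits <- sweep(A1 %*% par$W2, 2, par$b2, "+")
  P <- exp(logits - apply(logits, 1, max))
  P <- P / rowSums(P)
  list(P = P, A1 = A1, h = h, cache = cache)
}

lstm_backward <- function(par, fw, y_idx) {
  P <- fw$P
  N <- nrow(P)
  H <- nrow(par$Wh)
  ii <- seq_len(H); fi <- H + ii; gi <- 2 * H + ii; oi <- 3 * H + ii
  dlogits <- P
  dlogits[cbind(seq_len(N), y_idx)] <- dlogits[cbind(seq_len(N), y_idx)] - 1
  dlogits <- dlogits / N
  gW2 <- crossprod(fw$A1, dlogits)
  gb2 <- colSums(dlogits)
  dA1 <- dlogits %*% t(par$W2)
  dZ1 <- dA1 * (1 - fw$A1^2)
  gW1 <- crossprod(fw$cache[[length(fw$cache)]]$o *
                     fw$cache[[length(fw$cache)]]$tc, dZ1)
  gb1 <- colSums(dZ1)
  dh <- dZ1 %*% t(par$W1)
  dc <- matrix(0, N, H)
  gWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  gWh <- matrix(0, H, 4 * H)
  gb <- numeric(4 * H)
  for (t in rev(seq_along(fw$cache))) {
    cc <- fw$cache[[t]]
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    do <- dh * cc$tc
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dZ <- matrix(0, N, 4 * H)
    dZ[, ii] <- di * cc$i * (1 - cc$i)
    dZ[, fi] <- df * cc$f * (1 - cc$f)
    dZ[, gi] <- dg * (1 - cc$g^2)
    dZ[, oi] <- do * cc$o * (1 - cc$o)
    gWx <- gWx + crossprod(cc$Xt, dZ)
    gWh <- gWh + crossprod(cc$h_prev, dZ)
    gb <- gb + colSums(dZ)
    dh <- dZ %*% t(par$Wh)
    dc <- dc * cc$f
  }
  list(Wx = gWx, Wh = gWh, b = gb, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

adam_step <- function(par, grads, st, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(par)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grads[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - b1^t)
    vhat <- st$v[[nm]] / (1 - b2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

nll_of <- function(P, y_idx) {
  -mean(log(P[cbind(seq_len(nrow(P)), y_idx)] + 1e-12))
}

# batched forward in chunks to bound memory
forward_in_chunks <- function(par, x, chunk = 2048L) {
  N <- dim(x)[1]
  P <- NULL
  at <- 1L
  while (at <= N) {
    sel <- at:min(N, at + chunk - 1L)
    fw <- lstm_forward(par, x[sel, , , drop = FALSE])
    P <- rbind(P, fw$P)
    at <- at + chunk
  }
  P
}

#' Train the recurrent glucose predictor
#'
#' Minimizes the categorical negative log-likelihood of the observed
#' next-step glucose with Adam. Feedback of the model's own predictions
#' (scheduled sampling) ramps linearly from 0 to `feedback_max` across
#' epochs: each epoch the model's one-step predictions for every position
#' are computed in a single pass and substituted into the glucose input
#' channel with the epoch's feedback probability.
#'
#' @param sequences A [build_sequences()] result.
#' @param cfg A [cgp_config()].
#' @param zero_features Optional integer vector of feature columns to zero
#'   out (used by the ablation harness).
#' @return A list of class `cgp_model`: trained parameters, the config,
#'   the glucose grid, per-epoch mean training loss, and the zeroed
#'   feature set.
#' @export
cgp_train <- function(sequences, cfg, zero_features = integer()) {
  set.seed(cfg$seed)
  L <- sequences$sequence_length
  D <- nrow(cgp_features)
  x0 <- sequences$x
  if (length(zero_features)) x0[, , zero_features] <- 0
  y_idx <- sequences$y_idx
  N <- sequences$n
  par <- lstm_init(D, cfg$lstm_units, cfg$dense_units,
                   length(cfg$glucose_grid))
  st <- list(m = lapply(par, function(p) p * 0),
             v = lapply(par, function(p) p * 0))
  step_t <- 0L
  losses <- numeric(cfg$epochs)
  g_scale <- cgp_features$scale[1]
  g_center <- cgp_features$center[1]
  for (epoch in seq_len(cfg$epochs)) {
    s <- if (cfg$epochs > 1) {
      cfg$feedback_max * (epoch - 1) / (cfg$epochs - 1)
    } else 0
    x_use <- x0
    if (s > 0) {
      # teacher predictions for every position, then mix into the glucose
      # channel; mixing is done per day so overlapping windows agree
      P <- forward_in_chunks(par, x0)
      pred <- as.vector(P %*% cfg$glucose_grid)
      override <- list()
      for (nm in names(sequences$days)) {
        dd <- sequences$days[[nm]]
        gmix <- dd$M[, 1]
        sel <- which(sequences$day == dd$day)
        use_pred <- stats::runif(length(sel)) < s
        gmix[sequences$pos[sel][use_pred]] <-
          (pred[sel][use_pred] - g_center) / g_scale
        override[[nm]] <- gmix
      }
      tn <- sequences_tensor(sequences$days, L, cfg$glucose_grid, override)
      x_use <- tn$x
      if (length(zero_features)) x_use[, , zero_features] <- 0
    }
    ord <- sample(N)
    ep_loss <- 0
    n_batch <- 0L
    for (b0 in seq(1, N, by = cfg$batch_size)) {
      sel <- ord[b0:min(N, b0 + cfg$batch_size - 1)]
      fw <- lstm_forward(par, x_use[sel, , , drop = FALSE],
                         keep_cache = TRUE)
      loss <- nll_of(fw$P, y_idx[sel])
      if (!is.finite(loss)) stop("NaN loss at epoch ", epoch)
      grads <- lstm_backward(par, fw, y_idx[sel])
      step_t <- step_t + 1L
      upd <- adam_step(par, grads, st, cfg$learning_rate, step_t)
      par <- upd$par
      st <- upd$st
      ep_loss <- ep_loss + loss
      n_batch <- n_batch + 1L
    }
    losses[epoch] <- ep_loss / n_batch
  }
  structure(
    list(par = par, cfg = cfg, grid = cfg$glucose_grid, losses = losses,
         zero_features = zero_features),
    class = "cgp_model"
  )
}

#' @export
print.cgp_model <- function(x, ...) {
  cat(sprintf(
    "<cgp_model> LSTM(%d) + dense(%d) -> %d-point grid; final loss %.3f\n",
    x$cfg$lstm_units, x$cfg$dense_units, length(x$grid),
    x$losses[length(x$losses)]))
  invisible(x)
}

# point predictions for a sequences object (optionally respecting the
# model's zeroed features)
cgp_predict_sequences <- function(model, sequences) {
  x <- sequences$x
  if (length(model$zero_features)) x[, , model$zero_features] <- 0
  P <- forward_in_chunks(model$par, x)
  as.vector(P %*% model$grid)
}

weighted_band <- function(P, grid, q) {
  cum <- t(apply(P, 1, cumsum))
  grid[apply(cum >= q, 1, which.max)]
}

make_distribution <- function(P, grid, time_min) {
  structure(
    list(probs = P, grid = grid, time_min = time_min,
         mean = as.vector(P %*% grid),
         p10 = weighted_band(P, grid, 0.10),
         p25 = weighted_band(P, grid, 0.25),
         p75 = weighted_band(P, grid, 0.75),
         p90 = weighted_band(P, grid, 0.90)),
    class = "prediction_distribution"
  )
}

#' @export
print.prediction_distribution <- function(x, ...) {
  cat(sprintf(
    "<prediction_distribution> %d steps x %d-point grid; mean %.0f-%.0f mg/dL\n",
    nrow(x$probs), length(x$grid), min(x$mean), max(x$mean)))
  invisible(x)
}

# run the model autoregressively: `exog` rows supply hr/exercise/time/
# nutrients per future step; predicted glucose is fed back
autoregress <- function(model, context, exog) {
  L <- model$cfg$sequence_length
  if (nrow(context) < L) stop("context must have at least ", L, " frames")
  W <- scale_frames(utils::tail(context, L))
  if (length(model$zero_features)) W[, model$zero_features] <- 0
  h <- nrow(exog)
  P <- matrix(0, h, length(model$grid))
  for (k in seq_len(h)) {
    fw <- lstm_forward(model$par, array(W, c(1, L, ncol(W))))
    P[k, ] <- fw$P
    ghat <- sum(fw$P * model$grid)
    row <- scale_frames(exog[k, , drop = FALSE])
    row[1, 1] <- (ghat - cgp_features$center[1]) / cgp_features$scale[1]
    if (length(model$zero_features)) row[, model$zero_features] <- 0
    W <- rbind(W[-1, , drop = FALSE], row)
  }
  make_distribution(P, model$grid, exog$time_min)
}

blank_frame <- function(time_min, glucose, hr) {
  tod <- time_min %% 1440
  df <- data.frame(day = floor(time_min / 1440) + 1, time_min = time_min,
                   glucose = glucose, hr = hr, exercise_min = 0,
                   sin_t = sin(2 * pi * tod / 1440),
                   cos_t = cos(2 * pi * tod / 1440))
  for (nm in nutrient_cols) df[[nm]] <- 0
  df
}

#' Post-meal glucose forecast
#'
#' Predicts the glycemic impact of a hypothetical meal 2 h into the
#' future without the meal being consumed: the meal's nutrients are placed
#' in the final context frame and the model is rolled forward
#' autoregressively, each step's point estimate feeding the next step's
#' glucose input.
#'
#' @param model A trained [cgp_train()] model.
#' @param context Frame data frame (as from [build_frames()]) with at
#'   least `sequence_length` rows ending at the meal time.
#' @param meal A [nutrient_vector()] describing the hypothetical meal.
#' @param horizon_steps Number of 15-min steps to forecast (default 8,
#'   i.e. 2 h).
#' @return A `prediction_distribution` with one row per step.
#' @export
predict_postprandial <- function(model, context, meal,
                                 horizon_steps = 8) {
  ctx <- context
  last <- nrow(ctx)
  for (nm in nutrient_cols) {
    ctx[[nm]][last] <- ctx[[nm]][last] + meal[[nm]]
  }
  step <- diff(ctx$time_min[(last - 1):last])
  future_t <- ctx$time_min[last] + step * seq_len(horizon_steps)
  exog <- blank_frame(future_t, glucose = 0, hr = ctx$hr[last])
  autoregress(model, ctx, exog)
}

#' Virtual CGM rollout
#'
#' Estimates a full glucose trajectory from food logs and heart rate
#' alone: after the initial context no CGM input is used - every step's
#' glucose input is the model's previous point estimate.
#'
#' @param model A trained [cgp_train()] model.
#' @param exog Frame data frame for the rollout span (e.g. 96 rows for
#'   24 h) supplying `time_min`, `hr`, `exercise_min` and nutrient
#'   columns; any `glucose` column is ignored.
#' @param init_glucose Glucose level (mg/dL) used to seed the context.
#' @param context Optional real context frames; when `NULL` a flat
#'   context at `init_glucose` is synthesized before the rollout start.
#' @return A `prediction_distribution` with one row per exog step.
#' @export
vcgm_rollout <- function(model, exog, init_glucose = 100, context = NULL) {
  L <- model$cfg$sequence_length
  if (is.null(context)) {
    step <- if (nrow(exog) > 1) diff(exog$time_min[1:2]) else 15
    t_ctx <- exog$time_min[1] - step * rev(seq_len(L))
    context <- blank_frame(t_ctx, glucose = init_glucose,
                           hr = exog$hr[1])
  }
  exog$glucose <- 0
  autoregress(model, context, exog)
}

#' Forecast evaluation metrics
#'
#' @param pred Point predictions (numeric vector, or a
#'   `prediction_distribution` whose mean is used).
#' @param actual Observed glucose on the same step grid.
#' @param window_steps Steps per evaluation window for the peak metric
#'   (default 8, i.e. 2 h).
#' @param max_shift Maximum lag (steps) searched by the shifted RMSE
#'   (default 2, i.e. +/-30 min); lag 0 is always included so
#'   `rmse_shifted <= rmse_point_by_point`.
#' @return One-row data frame: `rmse_point_by_point`, `rmse_shifted`,
#'   `rmse_peak`, `percent_error` (MAPE, %), `correlation`.
#' @export
cgp_evaluate <- function(pred, actual, window_steps = 8, max_shift = 2) {
  if (inherits(pred, "prediction_distribution")) pred <- pred$mean
  if (length(pred) != length(actual)) stop("length mismatch")
  n <- length(pred)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  r_pbp <- rmse(pred, actual)
  shifts <- -max_shift:max_shift
  r_shift <- min(vapply(shifts, function(s) {
    if (s >= 0) {
      a <- pred[(1 + s):n]; b <- actual[1:(n - s)]
    } else {
      a <- pred[1:(n + s)]; b <- actual[(1 - s):n]
    }
    rmse(a, b)
  }, 0))
  starts <- seq(1, n, by = window_steps)
  peaks <- vapply(starts, function(s0) {
    sel <- s0:min(n, s0 + window_steps - 1)
    max(pred[sel]) - max(actual[sel])
  }, 0)
  data.frame(
    rmse_point_by_point = r_pbp,
    rmse_shifted = r_shift,
    rmse_peak = sqrt(mean(peaks^2)),
    percent_error = 100 * mean(abs(pred - actual) / actual),
    correlation = if (stats::sd(pred) > 0 && stats::sd(actual) > 0) {
      stats::cor(pred, actual)
    } else NA_real_)
}

# train on one split, report held-out point RMSE
train_eval_rmse <- function(train_seq, test_seq, cfg, zero_features) {
  model <- cgp_train(train_seq, cfg, zero_features = zero_features)
  pred <- cgp_predict_sequences(model, test_seq)
  sqrt(mean((pred - test_seq$y)^2))
}

# split a record's complete days into train and held-out tails
split_days <- function(record, holdout_frac = 0.25) {
  ok <- complete_days(record)
  n_test <- max(1, round(holdout_frac * length(ok)))
  list(train = utils::head(ok, length(ok) - n_test),
       test = utils::tail(ok, n_test))
}

#' Ablation analysis of feature-group importance
#'
#' Retrains the model with feature groups zeroed to measure each group's
#' contribution. In `"remove_most_important"` mode the harness greedily
#' removes, at each step, the group whose removal degrades held-out RMSE
#' the most, yielding an importance ranking and an RMSE ladder. In
#' `"reverse"` mode it starts from a glucose-history-only model and
#' greedily adds the group that improves RMSE the most. Glucose history is
#' always retained.
#'
#' @param record A [participant_record()] with enough complete days.
#' @param cfg A [cgp_config()].
#' @param mode `"remove_most_important"` or `"reverse"`.
#' @param holdout_frac Fraction of complete days held out for evaluation.
#' @param max_steps Number of greedy steps to take (default: all groups);
#'   `max_steps = 1` yields just the most (or, in reverse mode, the most
#'   informative first) group.
#' @return List with `mode`, `ranking` (most important first), `ladder`
#'   (data frame of step, group, rmse) and `rmse_full` /
#'   `rmse_glucose_only` reference points.
#' @export
cgp_ablation <- function(record, cfg,
                         mode = c("remove_most_important", "reverse"),
                         holdout_frac = 0.25, max_steps = Inf) {
  mode <- match.arg(mode)
  sp <- split_days(record, holdout_frac)
  train_seq <- build_sequences(record, cfg, days = sp$train,
                               min_complete_days = 1)
  test_seq <- build_sequences(record, cfg, days = sp$test,
                              min_complete_days = 1)
  groups <- cgp_feature_groups()
  groups <- groups[setdiff(names(groups), "glucose")]
  ev <- function(zero) train_eval_rmse(train_seq, test_seq, cfg, zero)
  rmse_full <- ev(integer())
  rmse_glu <- ev(unlist(groups, use.names = FALSE))
  ladder <- list()
  n_steps <- min(max_steps, length(groups))
  if (mode == "remove_most_important") {
    removed <- integer()
    remaining <- names(groups)
    for (step in seq_len(n_steps)) {
      rmses <- vapply(remaining, function(g) {
        ev(c(removed, groups[[g]]))
      }, 0)
      worst <- remaining[which.max(rmses)]
      ladder[[step]] <- data.frame(step = step, group = worst,
                                   rmse = max(rmses))
      removed <- c(removed, groups[[worst]])
      remaining <- setdiff(remaining, worst)
    }
    ranking <- vapply(ladder, function(r) r$group, "")
  } else {
    added <- character()
    remaining <- names(groups)
    for (step in seq_len(n_steps)) {
      rmses <- vapply(remaining, function(g) {
        keep <- c(added, g)
        ev(unlist(groups[setdiff(names(groups), keep)], use.names = FALSE))
      }, 0)
      best <- remaining[which.min(rmses)]
      ladder[[step]] <- data.frame(step = step, group = best,
                                   rmse = min(rmses))
      added <- c(added, best)
      remaining <- setdiff(remaining, best)
    }
    ranking <- rev(vapply(ladder, function(r) r$group, ""))
  }
  list(mode = mode, ranking = ranking, ladder = do.call(rbind, ladder),
       rmse_full = rmse_full, rmse_glucose_only = rmse_glu)
}

#' Per-user hyperparameter tuning
#'
#' Seeded random search over LSTM size, learning rate and sequence length,
#' selecting the candidate with the lowest validation negative
#' log-likelihood on the user's held-out days. Returns the base config
#' unchanged when no candidate beats it or when the budget is zero.
#'
#' @param record A [participant_record()] passing the complete-day rule.
#' @param base_cfg A [cgp_config()].
#' @param budget Number of random candidates to evaluate.
#' @param seed Search seed (default: the base config's).
#' @param holdout_frac Fraction of complete days used for validation.
#' @return List with `cfg` (the selected config), `val_nll`, and the
#'   candidate table.
#' @export
per_user_tune <- function(record, base_cfg, budget = 5,
                          seed = base_cfg$seed, holdout_frac = 0.25) {
  sp <- split_days(record, holdout_frac)
  val_nll <- function(cfg) {
    tr <- build_sequences(record, cfg, days = sp$train,
                          min_complete_days = 1)
    te <- build_sequences(record, cfg, days = sp$test,
                          min_complete_days = 1)
    model <- cgp_train(tr, cfg)
    x <- te$x
    P <- forward_in_chunks(model$par, x)
    nll_of(P, te$y_idx)
  }
  base_nll <- val_nll(base_cfg)
  best <- list(cfg = base_cfg, val_nll = base_nll)
  cand <- data.frame()
  if (budget > 0) {
    set.seed(seed)
    draws <- data.frame(
      lstm_units = sample(c(8L, 12L, 16L, 24L), budget, replace = TRUE),
      learning_rate = exp(stats::runif(budget, log(0.005), log(0.05))),
      sequence_length = sample(c(8L, 12L, 16L, 24L), budget,
                               replace = TRUE))
    for (i in seq_len(budget)) {
      cfg_i <- base_cfg
      cfg_i$lstm_units <- draws$lstm_units[i]
      cfg_i$learning_rate <- draws$learning_rate[i]
      cfg_i$sequence_length <- draws$sequence_length[i]
      nll_i <- val_nll(cfg_i)
      cand <- rbind(cand, cbind(draws[i, ], val_nll = nll_i))
      if (nll_i < best$val_nll) best <- list(cfg = cfg_i, val_nll = nll_i)
    }
  }
  list(cfg = best$cfg, val_nll = best$val_nll, base_nll = base_nll,
       candidates = cand)
}
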