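# fixture builders shared across test files; everything is generated in code

# paired cow-days from explicit components
make_pairs <- function(t_am, x_am, x_pm, cow_id = NULL) {
  n <- length(t_am)
  data.frame(
    cow_id = if (is.null(cow_id)) sprintf("c%03d", seq_len(n)) else cow_id,
    t_am = t_am, t_pm = 24 - t_am,
    x_am = x_am, x_pm = x_pm, y = x_am + x_pm, dim = 150
  )
}

pairs_records <- function(pairs) {
  ampmilk:::pairs_to_records(pairs)
}

# unpaired record rows lying exactly on a linear daily-yield surface
# y = alpha_j + beta t + b x  (free grid, so the fit is full rank)
linear_surface_records <- function(alpha_am, alpha_pm, beta, b,
                                   t = seq(9.5, 14.5, by = 0.5),
                                   x = c(8, 10, 12, 14)) {
  grid <- expand.grid(session = c("AM", "PM"), t = t, x = x,
                      stringsAsFactors = FALSE)
  alpha <- ifelse(grid$session == "AM", alpha_am, alpha_pm)
  y <- alpha + beta * grid$t + b * grid$x
  data.frame(
    cow_id = sprintf("r%03d", seq_len(nrow(grid))),
    session = grid$session, interval_h = grid$t,
    single_yield_kg = grid$x, daily_yield_kg = pmax(y, grid$x + 0.01)
  )
}

# record rows on an exact exponential surface log y = alpha_j + beta t + b log x
exp_surface_records <- function(alpha_am, alpha_pm, beta, b,
                                t = seq(9.5, 14.5, by = 0.5),
                                x = c(8, 10, 12, 14)) {
  grid <- expand.grid(session = c("AM", "PM"), t = t, x = x,
                      stringsAsFactors = FALSE)
  alpha <- ifelse(grid$session == "AM", alpha_am, alpha_pm)
  y <- exp(alpha + beta * grid$t + b * log(grid$x))
  data.frame(
    cow_id = sprintf("r%03d", seq_len(nrow(grid))),
    session = grid$session, interval_h = grid$t,
    single_yield_kg = grid$x, daily_yield_kg = pmax(y, grid$x + 0.01)
  )
}

# record rows with an exact single-milking proportion alpha_j + beta t
proportion_surface_records <- function(alpha_am, alpha_pm, beta,
                                       t_am = seq(10, 14, by = 0.5),
                                       y = c(18, 22, 26)) {
  grid <- expand.grid(t_am = t_am, y = y)
  p_am <- alpha_am + beta * grid$t_am
  p_pm <- alpha_pm + beta * (24 - grid$t_am)
  # proportions of a cow-day need not sum to 1 on an arbitrary surface;
  # build unpaired rows so the fit sees the surface exactly
  data.frame(
    cow_id = sprintf("r%03d", seq_len(2 * nrow(grid))),
    session = rep(c("AM", "PM"), each = nrow(grid)),
    interval_h = c(grid$t_am, 24 - grid$t_am),
    single_yield_kg = c(p_am * grid$y, p_pm * grid$y),
    daily_yield_kg = rep(grid$y, 2)
  )
}

# coefficient-model objects built directly (no fitting), for identity checks
manual_lr_model <- function(alpha_am, alpha_pm, beta, b, d0 = 150) {
  structure(list(alpha_am = alpha_am, alpha_pm = alpha_pm, beta = beta,
                 gamma = NA_real_, d0 = d0, b = b, se = NULL,
                 sigma2 = NA_real_, n = 0L, lm_fit = NULL),
            class = "lr_model")
}

manual_exp_model <- function(alpha_am, alpha_pm, beta, b) {
  structure(list(alpha_am = alpha_am, alpha_pm = alpha_pm, beta = beta,
                 b = b, se = NULL, sigma2 = NA_real_, n = 0L, lm_fit = NULL),
            class = "exp_model")
}

manual_proportion_model <- function(alpha_am, alpha_pm, beta) {
  structure(list(alpha_am = alpha_am, alpha_pm = alpha_pm, beta = beta,
                 beta_pm = NA_real_, se = NULL, sigma2 = NA_real_, n = 0L,
                 lm_fit = NULL),
            class = "proportion_model")
}

# reference herds reused across files (simulated once per test run)
small_herd <- function(n = 400, seed = 7, noise = NULL) {
  p <- if (is.null(noise)) sim_params(n_cows = n, seed = seed) else
    sim_params(n_cows = n, seed = seed, partition_noise_sd_kg = noise)
  simulate_herd(p)
}
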