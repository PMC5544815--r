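#' Cardiac cell models
#'
#' Constructs a single-cell action-potential model used as the nodal reaction
#' term of the surface propagation simulator. Two models are provided:
#'
#' * `"fhn"` - the two-variable FitzHugh-Nagumo oscillator in its excitable
#'   regime, `dv/dt = c (v - v^3/3 - w) + I`,
#'   `dw/dt = c eps (v + beta0 - gamma w)`, with rate constant `c` in 1/ms so
#'   that the upstroke lasts a few milliseconds and the action potential
#'   150-200 ms. Its dimensionless voltage is mapped affinely to millivolts so
#'   that the resting state is exactly -80 mV and the canonical single-cell
#'   peak is +20 mV.
#' * `"lr92"` - the eight-variable Luo-Rudy (1991) mammalian ventricular
#'   model (fast sodium, slow inward calcium, time-dependent and
#'   time-independent potassium, plateau and background currents), natively
#'   in mV/ms. Its resting potential is close to -84 mV.
#'
#' The resting state is computed as an exact equilibrium of the model
#' equations (polynomial root for FHN; nested root-finding over membrane
#' voltage and intracellular calcium for LR92), so an unstimulated cell stays
#' at rest to solver precision.
#'
#' @param name `"fhn"` or `"lr92"`.
#' @param ... parameter overrides. For `"fhn"`: `rate` (1/ms, default 0.4),
#'   `eps` (default 0.0125), `beta0` (0.7), `gamma` (0.8).
#' @return Object of class `cell_model`: list with `name`, `n_state`,
#'   `state_names`, `params`, `rest` (equilibrium state vector), `v_index`,
#'   `to_mv` / `scale` (affine map of the voltage variable to mV),
#'   `rhs(state, stimulus)`, `step(state, dt, i_ext)` (one explicit
#'   integration substep; `i_ext` is added to the voltage equation),
#'   and `default_stim_amplitude`.
#' @export
cell_model <- function(name = c("fhn", "lr92"), ...) {
  name <- match.arg(name)
  switch(name, fhn = fhn_model(...), lr92 = lr92_model(...))
}

#' Evaluate a cell model's state derivative
#'
#' @param model a [cell_model()].
#' @param state state vector (length `model$n_state`) or matrix
#'   (`n_state` x n_cells).
#' @param stimulus external current added to the voltage equation (model
#'   units per ms); scalar or per-cell vector.
#' @return Derivative of the state with the same shape as `state`.
#' @export
cell_model_rhs <- function(model, state, stimulus = 0) {
  vec <- is.null(dim(state))
  s <- if (vec) matrix(state, ncol = 1L) else state
  if (nrow(s) != model$n_state) stop("state dimension does not match model")
  if (any(!is.finite(s))) stop("numerical error: non-finite state")
  d <- model$rhs(s, stimulus)
  if (vec) d[, 1] else d
}

fhn_model <- function(rate = 0.4, eps = 0.0125, beta0 = 0.7, gamma = 0.8) {
  # rest: v - v^3/3 - w = 0 with w = (v + beta0)/gamma
  rts <- polyroot(c(beta0 / gamma, 1 / gamma - 1, 0, 1 / 3))
  v_rest <- Re(rts[which.min(abs(Im(rts)))])
  w_rest <- (v_rest + beta0) / gamma
  rhs <- function(state, stimulus = 0) {
    v <- state[1L, ]; w <- state[2L, ]
    rbind(rate * (v - v^3 / 3 - w) + stimulus,
          rate * eps * (v + beta0 - gamma * w))
  }
  # canonical single-cell peak under the reference stimulus protocol;
  # defines the +20 mV end of the affine voltage map
  v_peak <- local({
    v <- v_rest; w <- w_rest; dt <- 0.01; pk <- v_rest
    for (i in seq_len(40000L)) {
      t <- (i - 1) * dt
      I <- if (t >= 10 && t < 12) 4 else 0
      dv <- rate * (v - v^3 / 3 - w) + I
      dw <- rate * eps * (v + beta0 - gamma * w)
      v <- v + dt * dv; w <- w + dt * dw
      if (v > pk) pk <- v
    }
    pk
  })
  slope <- 100 / (v_peak - v_rest)
  intercept <- -80 - slope * v_rest
  step <- function(state, dt, i_ext = 0) {
    d <- rhs(state)
    d[1L, ] <- d[1L, ] + i_ext
    state + dt * d
  }
  structure(list(name = "fhn", n_state = 2L, state_names = c("v", "w"),
                 params = list(rate = rate, eps = eps, beta0 = beta0, gamma = gamma),
                 rest = c(v = v_rest, w = w_rest), v_index = 1L,
                 scale = c(intercept = intercept, slope = slope),
                 to_mv = function(v) intercept + slope * v,
                 rhs = rhs, step = step,
                 default_stim_amplitude = 4, default_substeps = 4L),
            class = "cell_model")
}

# ---- Luo-Rudy 1991 guinea-pig ventricular model -----------------------------

lr92_model <- function() {
  p <- list(RTF = 8.314 * 310 / 96.485,  # mV
            Nao = 140, Nai = 18, Ko = 5.4, Ki = 145, PRNaK = 0.01833,
            GNa = 23, Gsi = 0.09, GKp = 0.0183, Gb = 0.03921, Eb = -59.87)
  p$ENa <- p$RTF * log(p$Nao / p$Nai)
  p$GK <- 0.282 * sqrt(p$Ko / 5.4)
  p$GK1 <- 0.6047 * sqrt(p$Ko / 5.4)
  p$EK <- p$RTF * log((p$Ko + p$PRNaK * p$Nao) / (p$Ki + p$PRNaK * p$Nai))
  p$EK1 <- p$RTF * log(p$Ko / p$Ki)

  rates <- function(V) lr92_rates(V)
  currents <- function(V, m, h, j, d, f, X, Cai) {
    Esi <- 7.7 - 13.0287 * log(Cai)
    INa <- p$GNa * m^3 * h * j * (V - p$ENa)
    Isi <- p$Gsi * d * f * (V - Esi)
    IK <- p$GK * X * lr92_xi(V) * (V - p$EK)
    ak1 <- 1.02 / (1 + exp(0.2385 * (V - p$EK1 - 59.215)))
    bk1 <- (0.49124 * exp(0.08032 * (V - p$EK1 + 5.476)) +
              exp(0.06175 * (V - p$EK1 - 594.31))) /
      (1 + exp(-0.5143 * (V - p$EK1 + 4.753)))
    IK1 <- p$GK1 * ak1 / (ak1 + bk1) * (V - p$EK1)
    Kp <- 1 / (1 + exp((7.488 - V) / 5.98))
    IKp <- p$GKp * Kp * (V - p$EK1)
    Ib <- p$Gb * (V - p$Eb)
    list(total = INa + Isi + IK + IK1 + IKp + Ib, Isi = Isi)
  }

  rhs <- function(state, stimulus = 0) {
    V <- state[1L, ]; m <- state[2L, ]; h <- state[3L, ]; j <- state[4L, ]
    d <- state[5L, ]; f <- state[6L, ]; X <- state[7L, ]; Cai <- state[8L, ]
    r <- rates(V)
    cur <- currents(V, m, h, j, d, f, X, Cai)
    rbind(-cur$total + stimulus,
          r$am * (1 - m) - r$bm * m,
          r$ah * (1 - h) - r$bh * h,
          r$aj * (1 - j) - r$bj * j,
          r$ad * (1 - d) - r$bd * d,
          r$af * (1 - f) - r$bf * f,
          r$aX * (1 - X) - r$bX * X,
          -1e-4 * cur$Isi + 0.07 * (1e-4 - Cai))
  }

  # hybrid substep: Rush-Larsen for the six gates, forward Euler for V and Cai
  step <- function(state, dt, i_ext = 0) {
    V <- state[1L, ]; Cai <- state[8L, ]
    r <- rates(V)
    cur <- currents(V, state[2L, ], state[3L, ], state[4L, ],
                    state[5L, ], state[6L, ], state[7L, ], Cai)
    gates <- list(c("am", "bm"), c("ah", "bh"), c("aj", "bj"),
                  c("ad", "bd"), c("af", "bf"), c("aX", "bX"))
    out <- state
    for (g in seq_along(gates)) {
      a <- r[[gates[[g]][1]]]; b <- r[[gates[[g]][2]]]
      tau <- 1 / (a + b)
      inf <- a * tau
      out[g + 1L, ] <- inf + (state[g + 1L, ] - inf) * exp(-dt / tau)
    }
    out[1L, ] <- V + dt * (-cur$total + i_ext)
    out[8L, ] <- Cai + dt * (-1e-4 * cur$Isi + 0.07 * (1e-4 - Cai))
    out
  }

  # exact resting equilibrium: gates at steady state, Cai from the calcium
  # balance (inner root), V from zero total current (outer root)
  cai_eq <- function(V) {
    r <- rates(V)
    d_inf <- r$ad / (r$ad + r$bd); f_inf <- r$af / (r$af + r$bf)
    g <- function(Cai) {
      Esi <- 7.7 - 13.0287 * log(Cai)
      Isi <- p$Gsi * d_inf * f_inf * (V - Esi)
      -1e-4 * Isi + 0.07 * (1e-4 - Cai)
    }
    stats::uniroot(g, c(1e-7, 1e-2), tol = 1e-14)$root
  }
  vres <- stats::uniroot(function(V) {
    r <- rates(V)
    st <- c(V, r$am / (r$am + r$bm), r$ah / (r$ah + r$bh), r$aj / (r$aj + r$bj),
            r$ad / (r$ad + r$bd), r$af / (r$af + r$bf), r$aX / (r$aX + r$bX),
            cai_eq(V))
    cur <- currents(V, st[2], st[3], st[4], st[5], st[6], st[7], st[8])
    -cur$total
  }, c(-95, -70), tol = 1e-13)$root
  r0 <- rates(vres)
  rest <- c(V = vres, m = r0$am / (r0$am + r0$bm), h = r0$ah / (r0$ah + r0$bh),
            j = r0$aj / (r0$aj + r0$bj), d = r0$ad / (r0$ad + r0$bd),
            f = r0$af / (r0$af + r0$bf), X = r0$aX / (r0$aX + r0$bX),
            Cai = cai_eq(vres))

  structure(list(name = "lr92", n_state = 8L,
                 state_names = c("V", "m", "h", "j", "d", "f", "X", "Cai"),
                 params = p, rest = rest, v_index = 1L,
                 scale = c(intercept = 0, slope = 1),
                 to_mv = function(v) v,
                 rhs = rhs, step = step,
                 default_stim_amplitude = 40, default_substeps = 50L),
            class = "cell_model")
}

# LR91 rate constants; singular points handled by their analytic limits
lr92_rates <- function(V) {
  dn <- V + 47.13
  am <- ifelse(abs(dn) < 1e-6, 3.2, 0.32 * dn / (1 - exp(-0.1 * dn)))
  bm <- 0.08 * exp(-V / 11)
  lo <- V < -40
  ah <- ifelse(lo, 0.135 * exp((80 + V) / -6.8), 0)
  bh <- ifelse(lo, 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V),
               1 / (0.13 * (1 + exp((V + 10.66) / -11.1))))
  aj <- ifelse(lo,
               (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
                 (V + 37.78) / (1 + exp(0.311 * (V + 79.23))),
               0)
  bj <- ifelse(lo,
               0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14))),
               0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32))))
  ad <- 0.095 * exp(-0.01 * (V - 5)) / (1 + exp(-0.072 * (V - 5)))
  bd <- 0.07 * exp(-0.017 * (V + 44)) / (1 + exp(0.05 * (V + 44)))
  af <- 0.012 * exp(-0.008 * (V + 28)) / (1 + exp(0.15 * (V + 28)))
  bf <- 0.0065 * exp(-0.02 * (V + 30)) / (1 + exp(-0.2 * (V + 30)))
  aX <- 0.0005 * exp(0.083 * (V + 50)) / (1 + exp(0.057 * (V + 50)))
  bX <- 0.0013 * exp(-0.06 * (V + 20)) / (1 + exp(-0.04 * (V + 20)))
  list(am = am, bm = bm, ah = ah, bh = bh, aj = aj, bj = bj,
       ad = ad, bd = bd, af = af, bf = bf, aX = aX, bX = bX)
}

lr92_xi <- function(V) {
  out <- ifelse(V > -100,
                2.837 * (exp(0.04 * (V + 77)) - 1) /
                  ((V + 77) * exp(0.04 * (V + 35))),
                1)
  sing <- abs(V + 77) < 1e-6
  if (any(sing)) out[sing] <- 2.837 * 0.04 / exp(0.04 * (-77 + 35))
  out
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("cell model '%s': %d state variables, resting V = %.2f mV\n",
              x$name, x$n_state, x$to_mv(x$rest[x$v_index])))
  invisible(x)
}
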