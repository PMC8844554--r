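# Independent oracles kept deliberately separate from the implementation:
# a fine-grid integrator for AUC QALYs, a sorting-based percentile rule,
# and exhaustive enumeration of a two-event annual-cycle tree.

# midpoint-rule numerical integral of the piecewise-linear utility curve
# under the same tail conventions (carry-forward; linear decline to zero at
# death), with accrual-year discounting
oracle_auc <- function(times, utilities, followup_end, death_time = NA,
                       discount_rate = 0, dt = 1e-4) {
  end <- min(followup_end, death_time, na.rm = TRUE)
  t <- times
  u <- utilities
  died <- !is.na(death_time) && death_time <= followup_end
  if (max(t) < end) {
    t <- c(t, end)
    u <- c(u, if (died) 0 else u[length(u)])
  }
  if (t[1] > 0) {
    t <- c(0, t)
    u <- c(u[1], u)
  }
  brk <- sort(unique(c(t, seq_len(ceiling(end)) - 1, end)))
  brk <- brk[brk >= 0 & brk <= end]
  total <- 0
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]
    b <- brk[i + 1]
    if (b <= a) next
    g <- seq(a, b, length.out = max(2, ceiling((b - a) / dt)))
    mids <- (g[-1] + g[-length(g)]) / 2
    vals <- approx(t, u, xout = mids, rule = 2)$y
    total <- total + sum(vals * diff(g)) / (1 + discount_rate)^floor(a + 1e-12)
  }
  total
}

# brute-force linear-interpolation percentile (the type-7 rule, written
# directly from its definition h = (n - 1) p + 1 on the sorted sample)
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Exhaustive expectation for an annual-cycle model with one complication
# (constant annual probability p_event, first event only) and death
# (constant annual probability p_death), over `horizon` years. Events and
# death are drawn independently each year; accrual happens for patients
# alive at the start of the year; the event-year decrement/cost applies in
# the year of occurrence and the ongoing ones in later years; death takes
# effect at the end of its year. Returns expected discounted cost, QALYs
# and life-years, plus exact per-patient variances for Monte-Carlo bands.
oracle_two_event_tree <- function(p_event, p_death, horizon, u0,
                                  dec_event, dec_ongoing, cost_event,
                                  cost_ongoing, background, rate_cost = 0,
                                  rate_eff = 0) {
  paths <- list(list(prob = 1, alive = TRUE, hist = FALSE,
                     cost = 0, qaly = 0, ly = 0))
  for (y in seq_len(horizon) - 1) {
    nxt <- list()
    for (pth in paths) {
      if (!pth$alive) {
        nxt[[length(nxt) + 1]] <- pth
        next
      }
      pe <- if (pth$hist) 0 else p_event
      for (ev in c(FALSE, TRUE)) {
        for (dd in c(FALSE, TRUE)) {
          pr <- pth$prob * (if (ev) pe else 1 - pe) *
            (if (dd) p_death else 1 - p_death)
          if (pr == 0) next
          util <- u0 - (if (ev) dec_event else 0) -
            (if (pth$hist) dec_ongoing else 0)
          cost <- background + (if (ev) cost_event else 0) +
            (if (pth$hist) cost_ongoing else 0)
          nxt[[length(nxt) + 1]] <- list(
            prob = pr, alive = !dd, hist = pth$hist || ev,
            cost = pth$cost + cost / (1 + rate_cost)^y,
            qaly = pth$qaly + util / (1 + rate_eff)^y,
            ly = pth$ly + 1 / (1 + rate_eff)^y)
        }
      }
    }
    # merge identical states to keep the tree small
    key <- vapply(nxt, function(p) paste(p$alive, p$hist, p$cost, p$qaly),
                  character(1))
    paths <- lapply(split(seq_along(nxt), key), function(i) {
      p <- nxt[[i[1]]]
      p$prob <- sum(vapply(nxt[i], `[[`, numeric(1), "prob"))
      p
    })
  }
  agg <- function(f) {
    v <- vapply(paths, `[[`, numeric(1), f)
    pr <- vapply(paths, `[[`, numeric(1), "prob")
    c(mean = sum(pr * v), var = sum(pr * v^2) - sum(pr * v)^2)
  }
  list(cost = agg("cost"), qaly = agg("qaly"), ly = agg("ly"))
}
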