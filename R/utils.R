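# Shared internal helpers: seeded noise draws, validation, seed derivation.

#' Multiplicative lognormal noise with unit mean
#'
#' Draws `n` lognormal multipliers with expectation 1 and coefficient of
#' variation `cv`. With `cv = 0` the multipliers are exactly 1, so zero-noise
#' generator runs reproduce their parameterised means bit-for-bit.
#'
#' @param n number of draws.
#' @param cv coefficient of variation (fraction, >= 0).
#' @return numeric vector of length `n`, all positive.
#' @keywords internal
#' @noRd
lnorm_noise <- function(n, cv) {
  stopifnot(is.numeric(cv), length(cv) == 1L, cv >= 0)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Derive a per-stage RNG seed from the master seed
#'
#' Mixes the stage name into the master seed so each pipeline stage gets an
#' independent, reproducible stream. The result stays inside the 32-bit
#' integer range R requires of `set.seed()`.
#'
#' @param seed master integer seed.
#' @param stage stage name (character scalar).
#' @return integer seed.
#' @keywords internal
#' @noRd
stage_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483647)
}

# Stops with a classed condition so callers/tests can match on class.
abort_boreff <- function(msg, class) {
  stop(structure(
    class = c(class, "boreff_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# scalar checks used across constructors
check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort_boreff(
      sprintf("`%s` must be a single integer >= %d (got %s)",
              name, min, paste(format(x), collapse = ", ")),
      "boreff_config_error"
    )
  }
  invisible(as.integer(x))
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort_boreff(
      sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi),
      "boreff_config_error"
    )
  }
  invisible(as.numeric(x))
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_boreff(sprintf("`%s` must be a single positive number", name),
                 "boreff_config_error")
  }
  invisible(as.numeric(x))
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-absorb assignment of grouping letters: groups that are not
#' significantly different (p >= alpha) share a letter. Deterministic in the
#' order of `levels`.
#'
#' @param pmat symmetric-ish matrix of pairwise p-values with dimnames, as
#'   returned (lower-triangular) by [stats::pairwise.t.test()].
#' @param levels group labels in display order.
#' @param alpha significance level.
#' @return named character vector of letter strings, one per level.
#' @keywords internal
#' @noRd
letter_groups <- function(pmat, levels, alpha = 0.05) {
  k <- length(levels)
  p_of <- function(a, b) {
    if (a == b) return(1)
    # pairwise.t.test gives a lower-triangular matrix; look up both ways
    v1 <- if (a %in% rownames(pmat) && b %in% colnames(pmat)) pmat[a, b] else NA
    v2 <- if (b %in% rownames(pmat) && a %in% colnames(pmat)) pmat[b, a] else NA
    out <- c(v1, v2)
    out <- out[!is.na(out)]
    if (length(out) == 0) 1 else out[1]
  }
  differ <- matrix(FALSE, k, k, dimnames = list(levels, levels))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) differ[i, j] <- p_of(levels[i], levels[j]) < alpha
  }
  # start with one group containing everything, split on contradictions
  groups <- list(seq_len(k))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j && differ[i, j]) {
      new_groups <- list()
      for (g in groups) {
        if (i %in% g && j %in% g) {
          new_groups <- c(new_groups, list(setdiff(g, i)), list(setdiff(g, j)))
        } else {
          new_groups <- c(new_groups, list(g))
        }
      }
      # absorb: drop groups contained in another
      keep <- rep(TRUE, length(new_groups))
      for (a in seq_along(new_groups)) for (b in seq_along(new_groups)) {
        if (a != b && keep[a] && all(new_groups[[a]] %in% new_groups[[b]]) &&
            length(new_groups[[a]]) < length(new_groups[[b]])) {
          keep[a] <- FALSE
        }
      }
      groups <- unique(new_groups[keep])
    }
  }
  out <- setNames(rep("", k), levels)
  for (gi in seq_along(groups)) {
    for (m in groups[[gi]]) out[m] <- paste0(out[m], letters[gi])
  }
  out
}
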