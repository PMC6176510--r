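# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: exhaustive search for affinity propagation,
# direct tally + textbook formulas for mutual information, central finite
# differences for gradients.

# exhaustive exemplar-subset search: over every non-empty subset E of points,
# net similarity = sum of preferences of E + sum over non-members of the best
# similarity to a member.  Returns the grouping (membership vector) of the
# best subset (first one found on ties).
ap_oracle_grouping <- function(values, preference) {
  n <- length(values)
  s <- -outer(values, values, "-")^2
  best <- -Inf
  best_labels <- NULL
  for (mask in 1:(2^n - 1)) {
    E <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    net <- length(E) * preference
    labels <- integer(n)
    for (i in seq_len(n)) {
      if (i %in% E) {
        labels[i] <- match(i, E)
      } else {
        j <- which.max(s[i, E])
        net <- net + s[i, E[j]]
        labels[i] <- j
      }
    }
    if (net > best + 1e-12) {
      best <- net
      best_labels <- labels
    }
  }
  best_labels
}

# grouping equality up to label renaming
same_grouping <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# brute-force MI in bits from two symbol sequences: direct tally, marginals,
# plain -sum p log2 p sums with explicit loops
mi_oracle_bits <- function(sx, sy) {
  n <- length(sx)
  ux <- sort(unique(sx)); uy <- sort(unique(sy))
  pxy <- matrix(0, length(ux), length(uy))
  for (t in seq_len(n)) {
    i <- match(sx[t], ux); j <- match(sy[t], uy)
    pxy[i, j] <- pxy[i, j] + 1
  }
  pxy <- pxy / n
  px <- rowSums(pxy); py <- colSums(pxy)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h(px) + h(py) - h(pxy)
}

# minimum |pre-activation| over every edge for a batch: the finite-difference
# oracle is only valid away from the rectifier kinks, so callers resample
# batches until this clears a margin.  Forward rule replicated independently.
min_abs_preact <- function(params, X) {
  L <- length(params$config$widths)
  A <- vector("list", L)
  A[[1]] <- X
  for (i in 2:L) A[[i]] <- matrix(0, nrow(X), params$config$widths[i])
  m <- Inf
  for (e in seq_along(params$edges)) {
    ed <- params$edges[[e]]
    z <- sweep(A[[ed$from]] %*% ed$w, 2, ed$b, "+")
    m <- min(m, min(abs(z)))
    A[[ed$to]] <- A[[ed$to]] + pmax(z, 0)
  }
  m
}

# central finite differences of the batch MSE loss over every parameter
fd_gradients <- function(params, X, y, eps = 1e-6) {
  loss_of <- function(p) loss_and_gradients(p, X, y)$loss
  lapply(seq_along(params$edges), function(e) {
    gw <- params$edges[[e]]$w
    for (idx in seq_along(gw)) {
      pp <- params; pp$edges[[e]]$w[idx] <- pp$edges[[e]]$w[idx] + eps
      pm <- params; pm$edges[[e]]$w[idx] <- pm$edges[[e]]$w[idx] - eps
      gw[idx] <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    }
    gb <- params$edges[[e]]$b
    for (idx in seq_along(gb)) {
      pp <- params; pp$edges[[e]]$b[idx] <- pp$edges[[e]]$b[idx] + eps
      pm <- params; pm$edges[[e]]$b[idx] <- pm$edges[[e]]$b[idx] - eps
      gb[idx] <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    }
    list(w = gw, b = gb)
  })
}

max_rel_err <- function(analytic, numeric, floor = 1e-8) {
  m <- 0
  for (e in seq_along(analytic)) {
    for (part in c("w", "b")) {
      a <- analytic[[e]][[part]]
      f <- numeric[[e]][[part]]
      keep <- abs(a) > floor | abs(f) > floor
      if (any(keep))
        m <- max(m, max(abs(a[keep] - f[keep]) /
                          pmax(abs(a[keep]), abs(f[keep]))))
    }
  }
  m
}
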