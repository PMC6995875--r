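#' @importFrom rlang abort warn inform %||%
#' @importFrom stats median setNames
NULL

# Cache for operator matrices and boundary matrices, keyed by expansion order
# (and refractive indices where relevant). These are pure functions of their
# keys, so memoization never changes results.
.shef_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, builder) {
  if (!is.null(.shef_cache[[key]])) return(.shef_cache[[key]])
  val <- builder()
  assign(key, val, envir = .shef_cache)
  val
}

#' Spherical-harmonic basis index table
#'
#' Enumerates the real spherical-harmonic basis functions used by the order-N
#' radiance expansion: degrees `l = 0..order`, azimuthal orders `m = 0..l`,
#' with a cosine- and (for m > 0) a sine-type function per (l, m). The table
#' has `(order + 1)^2` rows, one per expansion coefficient.
#'
#' @param order Expansion order N (integer >= 1).
#' @return A tibble with columns `l`, `m`, `type` ("c" or "s").
#' @export
sh_index_table <- function(order) {
  stopifnot(is.numeric(order), length(order) == 1, order >= 1)
  l <- integer(0); m <- integer(0); type <- character(0)
  for (li in 0:order) for (mi in 0:li) {
    l <- c(l, li); m <- c(m, mi); type <- c(type, "c")
    if (mi > 0) { l <- c(l, li); m <- c(m, mi); type <- c(type, "s") }
  }
  tibble::tibble(l = l, m = m, type = type)
}

# Orthonormal associated Legendre functions f_lm(mu), no Condon-Shortley
# phase, normalized so that int_{-1}^{1} f_lm f_l'm dmu = delta_{ll'}.
# Returns a list indexed by m+1; element m+1 is a matrix with length(mu) rows
# and columns l = m..order. Standard stable three-term recursion.
norm_assoc_legendre <- function(order, mu) {
  s <- sqrt(pmax(0, 1 - mu^2))
  out <- vector("list", order + 1)
  fmm <- rep(1 / sqrt(2), length(mu))
  for (m in 0:order) {
    if (m > 0) fmm <- sqrt((2 * m + 1) / (2 * m)) * s * fmm
    block <- matrix(0, length(mu), order - m + 1)
    block[, 1] <- fmm
    if (order > m) {
      block[, 2] <- sqrt(2 * m + 3) * mu * fmm
      if (order > m + 1) {
        for (l in (m + 2):order) {
          c1 <- sqrt((2 * l - 1) * (2 * l + 1) / ((l - m) * (l + m)))
          c2 <- sqrt((2 * l + 1) * (l - 1 - m) * (l - 1 + m) /
                       ((2 * l - 3) * (l - m) * (l + m)))
          block[, l - m + 1] <- c1 * mu * block[, l - m] - c2 * block[, l - m - 1]
        }
      }
    }
    out[[m + 1]] <- block
  }
  out
}

# Evaluate all (order+1)^2 real spherical harmonics on a (mu, phi) product
# grid. Returns a K x (n_mu * n_phi) matrix; node (i, j) maps to column
# (j - 1) * n_mu + i.
sh_eval_grid <- function(idx, order, mu, phi) {
  f <- norm_assoc_legendre(order, mu)
  n_mu <- length(mu); n_phi <- length(phi)
  K <- nrow(idx)
  Y <- matrix(0, K, n_mu * n_phi)
  for (k in seq_len(K)) {
    l <- idx$l[k]; m <- idx$m[k]
    fl <- f[[m + 1]][, l - m + 1]
    az <- if (m == 0) rep(1 / sqrt(2 * pi), n_phi)
          else if (idx$type[k] == "c") cos(m * phi) / sqrt(pi)
          else sin(m * phi) / sqrt(pi)
    Y[k, ] <- as.vector(outer(fl, az))
  }
  Y
}

# Streaming (A_z), transverse-coupling (A_x) and related fixed matrices for a
# given expansion order, built by quadrature that is exact for the polynomial
# integrands involved. Cached per order.
sh_operators <- function(order) {
  cache_get_or(paste0("ops_", order), function() {
    idx <- sh_index_table(order)
    K <- nrow(idx)
    n_mu <- 2 * order + 16
    n_phi <- 4 * order + 8
    gl <- pracma::gaussLegendre(n_mu, -1, 1)
    phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
    w_phi <- 2 * pi / n_phi
    Y <- sh_eval_grid(idx, order, gl$x, phi)
    w <- as.vector(outer(gl$w, rep(w_phi, n_phi)))
    mu_z <- as.vector(outer(gl$x, rep(1, n_phi)))
    mu_x <- as.vector(outer(sqrt(pmax(0, 1 - gl$x^2)), cos(phi)))
    Az <- Y %*% (t(Y) * (w * mu_z))
    Ax <- Y %*% (t(Y) * (w * mu_x))
    Az <- (Az + t(Az)) / 2
    Ax <- (Ax + t(Ax)) / 2
    Az[abs(Az) < 1e-12] <- 0
    Ax[abs(Ax) < 1e-12] <- 0

    # Similarity transform diag(i^(m %% 2)) turns i*k*A_x into a real matrix
    # because A_x couples only basis functions of opposite m-parity; encode it
    # as a signed A_x: entries into even-m rows from odd-m columns flip sign.
    p <- idx$m %% 2
    if (max(abs(Ax[outer(p, p, "==")])) > 1e-10) {
      abort("transverse coupling matrix violates the m-parity selection rule",
            class = "sfdlayers_internal_error")
    }
    sign_mat <- matrix(1, K, K)
    sign_mat[, p == 1] <- -1
    Ax_signed <- Ax * sign_mat

    # Interface-condition basis: orthonormal basis of range(A_z), built
    # per (m, type) block so each basis vector lives in a single block.
    blocks <- split(seq_len(K), paste(idx$m, idx$type))
    Ut <- NULL
    n_null <- 0L
    for (b in blocks) {
      Ab <- Az[b, b, drop = FALSE]
      e <- eigen(Ab, symmetric = TRUE)
      keep <- abs(e$values) > 1e-10 * max(1, max(abs(e$values)))
      n_null <- n_null + sum(!keep)
      if (any(keep)) {
        rows <- matrix(0, sum(keep), K)
        rows[, b] <- t(e$vectors[, keep, drop = FALSE])
        Ut <- rbind(Ut, rows)
      }
    }

    # Direction-of-incidence evaluation Y(z-hat): only m = 0 survives.
    Yz <- numeric(K)
    m0 <- which(idx$m == 0)
    Yz[m0] <- sqrt((2 * idx$l[m0] + 1) / (4 * pi))

    list(idx = idx, K = K, Az = Az, Ax = Ax, Ax_signed = Ax_signed,
         Ut = Ut, n_null = n_null, Yz = Yz,
         marshak_rows = which((idx$l + idx$m) %% 2 == 1))
  })
}

# Unpolarized Fresnel reflection coefficient for radiance incident from medium
# n1 onto medium n2 with direction cosine mu (relative to the normal).
fresnel_reflectance <- function(mu, n1, n2) {
  mu <- pmin(1, pmax(0, mu))
  st2 <- (n1 / n2)^2 * (1 - mu^2)
  R <- rep(1, length(mu))
  ok <- st2 < 1
  if (any(ok)) {
    ct <- sqrt(1 - st2[ok])
    ci <- mu[ok]
    rs <- (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct)
    rp <- (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci)
    R[ok] <- (rs^2 + rp^2) / 2
  }
  R
}

# Gauss-Legendre nodes on [0, 1], split at the total-internal-reflection
# critical cosine so the Fresnel kink never crosses a panel.
half_range_nodes <- function(n_med, n_amb, n_per_panel = 48) {
  mu_c <- if (n_med > n_amb) sqrt(1 - (n_amb / n_med)^2) else 0
  if (mu_c > 1e-9 && mu_c < 1 - 1e-9) {
    g1 <- pracma::gaussLegendre(n_per_panel, 0, mu_c)
    g2 <- pracma::gaussLegendre(n_per_panel, mu_c, 1)
    list(x = c(g1$x, g2$x), w = c(g1$w, g2$w))
  } else {
    pracma::gaussLegendre(2 * n_per_panel, 0, 1)
  }
}

# Marshak half-range boundary matrix at the top surface, incorporating Fresnel
# internal reflection for the medium/ambient index step. Rows are the
# odd-(l+m) projections over the incoming hemisphere; one row per condition,
# columns over all basis coefficients. Cached per (order, n_med, n_amb).
marshak_matrix <- function(order, n_med, n_amb) {
  key <- sprintf("marshak_%d_%.10g_%.10g", order, n_med, n_amb)
  cache_get_or(key, function() {
    ops <- sh_operators(order)
    idx <- ops$idx
    q <- half_range_nodes(n_med, n_amb)
    f <- norm_assoc_legendre(order, q$x)
    RF <- fresnel_reflectance(q$x, n_med, n_amb)
    rows <- ops$marshak_rows
    M <- matrix(0, length(rows), ops$K)
    for (r in seq_along(rows)) {
      k1 <- rows[r]
      l1 <- idx$l[k1]; m1 <- idx$m[k1]; t1 <- idx$type[k1]
      f1 <- f[[m1 + 1]][, l1 - m1 + 1]
      cols <- which(idx$m == m1 & idx$type == t1)
      for (k2 in cols) {
        l2 <- idx$l[k2]
        f2 <- f[[m1 + 1]][, l2 - m1 + 1]
        h  <- sum(q$w * f1 * f2)
        hr <- sum(q$w * RF * f1 * f2)
        M[r, k2] <- h - (-1)^(l2 + m1) * hr
      }
    }
    M
  })
}

# Hemispheric Fresnel-transmission exit weights: Rd = sum(t * c(0)). Only
# m = 0 coefficients contribute (azimuthal integral kills m > 0).
exit_weights <- function(order, n_med, n_amb) {
  key <- sprintf("exit_%d_%.10g_%.10g", order, n_med, n_amb)
  cache_get_or(key, function() {
    ops <- sh_operators(order)
    idx <- ops$idx
    q <- half_range_nodes(n_med, n_amb)
    f <- norm_assoc_legendre(order, -q$x)  # outgoing directions mu_z = -mu
    Tf <- 1 - fresnel_reflectance(q$x, n_med, n_amb)
    tw <- numeric(ops$K)
    m0 <- which(idx$m == 0)
    for (k in m0) {
      l <- idx$l[k]
      tw[k] <- sqrt(2 * pi) * sum(q$w * Tf * q$x * f[[1]][, l + 1])
    }
    tw
  })
}
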