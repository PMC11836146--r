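#' Element deformation histories for one simulation
#'
#' A `strain_sim` bundles the finite-element-like output of one impact
#' simulation: per-element deformation-gradient time histories, per
#' white-matter-element reference fiber unit vectors, and region labels.
#'
#' @param F numeric array `n_elem x n_t x 3 x 3` of deformation gradients;
#'   `F[, 1, , ]` must be the identity (undeformed start).
#' @param time time samples in ms.
#' @param region character vector of region labels from
#'   [strain_regions()]; white matter is the union of `white_matter`,
#'   `corpus_callosum` and `cerebellum_wm`.
#' @param fiber `n_elem x 3` matrix of reference fiber unit vectors; rows may
#'   be `NA` for non-white-matter elements.
#' @param element_id integer element ids (default `1:n_elem`).
#' @param helmet_id,location metadata labels.
#' @return a `strain_sim` list.
#' @export
strain_sim <- function(F, time, region, fiber = NULL,
                       element_id = NULL, helmet_id = NA_character_,
                       location = NA_character_) {
  stopifnot(length(dim(F)) == 4, dim(F)[3] == 3, dim(F)[4] == 3)
  n_elem <- dim(F)[1]
  n_t <- dim(F)[2]
  if (length(time) != n_t) stop_data("time length must match dim(F)[2]")
  if (length(region) != n_elem) stop_data("region length must match dim(F)[1]")
  unknown <- setdiff(unique(region), strain_regions())
  if (length(unknown) > 0) {
    stop_parameter(sprintf(
      "unknown region label(s) %s; known: %s",
      paste(unknown, collapse = ", "), paste(strain_regions(), collapse = ", ")
    ))
  }
  if (is.null(element_id)) element_id <- seq_len(n_elem)
  if (is.null(fiber)) fiber <- matrix(NA_real_, n_elem, 3)
  wm <- is_white_matter(region)
  nf <- sqrt(rowSums(fiber^2))
  bad <- wm & (!is.finite(nf) | abs(nf - 1) > 1e-9)
  if (any(bad)) {
    stop_data(sprintf(
      "white-matter element %d lacks a unit fiber vector", element_id[which(bad)[1]]
    ))
  }
  structure(
    list(
      F = F, time = time, region = region, fiber = fiber,
      element_id = as.integer(element_id),
      helmet_id = helmet_id, location = location
    ),
    class = "strain_sim"
  )
}

#' @rdname strain_sim
#' @export
strain_regions <- function() {
  c("brain", "white_matter", "corpus_callosum", "cerebellum_wm", "other")
}

#' @rdname strain_sim
#' @export
is_white_matter <- function(region) {
  region %in% c("white_matter", "corpus_callosum", "cerebellum_wm")
}

#' @export
print.strain_sim <- function(x, ...) {
  cat(sprintf(
    "<strain_sim> helmet %s, %s: %d elements (%d WM), %d time steps over %g ms\n",
    x$helmet_id, x$location, length(x$element_id),
    sum(is_white_matter(x$region)), length(x$time), max(x$time)
  ))
  invisible(x)
}

#' Green-Lagrange strain tensor of one deformation gradient
#'
#' `E = (t(F) %*% F - I) / 2`, symmetric by construction and exactly zero
#' under rigid motion.
#'
#' @param F a 3x3 deformation gradient with positive determinant.
#' @return symmetric 3x3 strain tensor.
#' @export
green_lagrange <- function(F) {
  if (det(F) <= 0) stop_data("deformation gradient with det(F) <= 0")
  (crossprod(F) - diag(3)) / 2
}

#' Deformed (real-time) fiber direction
#'
#' The reference fiber `a0` convected by the deformation and renormalised:
#' `F a0 / |F a0|`.
#'
#' @param F 3x3 deformation gradient.
#' @param a0 unit reference fiber vector.
#' @return unit vector in the deformed configuration.
#' @export
realtime_fiber_direction <- function(F, a0) {
  v <- as.numeric(F %*% a0)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop_numerical("fiber image has vanishing norm")
  v / nv
}

# ---- vectorised tensor kernels -------------------------------------------
# All kernels operate on per-component matrices of shape n_elem x n_t.

# Green-Lagrange components from deformation-gradient components.
gl_components <- function(Fc) {
  with(Fc, {
    list(
      E11 = (F11 * F11 + F21 * F21 + F31 * F31 - 1) / 2,
      E22 = (F12 * F12 + F22 * F22 + F32 * F32 - 1) / 2,
      E33 = (F13 * F13 + F23 * F23 + F33 * F33 - 1) / 2,
      E12 = (F11 * F12 + F21 * F22 + F31 * F32) / 2,
      E13 = (F11 * F13 + F21 * F23 + F31 * F33) / 2,
      E23 = (F12 * F13 + F22 * F23 + F32 * F33) / 2
    )
  })
}

det3_components <- function(Fc) {
  with(Fc, {
    F11 * (F22 * F33 - F23 * F32) -
      F12 * (F21 * F33 - F23 * F31) +
      F13 * (F21 * F32 - F22 * F31)
  })
}

# Largest eigenvalue of a symmetric 3x3 tensor, closed form (trigonometric),
# applied elementwise to component matrices.
sym3_max_eig <- function(E) {
  with(E, {
    q <- (E11 + E22 + E33) / 3
    p2 <- (E11 - q)^2 + (E22 - q)^2 + (E33 - q)^2 +
      2 * (E12^2 + E13^2 + E23^2)
    p <- sqrt(pmax(p2, 0) / 6)
    # B = (E - qI)/p; det(B)/2 drives the phase angle
    safe_p <- ifelse(p > 0, p, 1)
    B11 <- (E11 - q) / safe_p
    B22 <- (E22 - q) / safe_p
    B33 <- (E33 - q) / safe_p
    B12 <- E12 / safe_p
    B13 <- E13 / safe_p
    B23 <- E23 / safe_p
    detB <- B11 * (B22 * B33 - B23^2) -
      B12 * (B12 * B33 - B23 * B13) +
      B13 * (B12 * B23 - B22 * B13)
    rr <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(rr) / 3
    lam <- q + 2 * p * cos(phi)
    ifelse(p > 0, lam, q)
  })
}

f_components <- function(F) {
  d <- dim(F)
  comp <- function(i, j) matrix(F[, , i, j], d[1], d[2])
  list(
    F11 = comp(1, 1), F12 = comp(1, 2), F13 = comp(1, 3),
    F21 = comp(2, 1), F22 = comp(2, 2), F23 = comp(2, 3),
    F31 = comp(3, 1), F32 = comp(3, 2), F33 = comp(3, 3)
  )
}

# Tract frame + rotated strain components for a block of elements.
# Fc: component matrices (n x n_t); a0: n x 3. Returns list of histories
# ton, tpn, tos, tps (n x n_t).
tract_components <- function(Fc, E, a0, realtime = TRUE) {
  a01 <- a0[, 1]
  a02 <- a0[, 2]
  a03 <- a0[, 3]
  if (realtime) {
    v1 <- Fc$F11 * a01 + Fc$F12 * a02 + Fc$F13 * a03
    v2 <- Fc$F21 * a01 + Fc$F22 * a02 + Fc$F23 * a03
    v3 <- Fc$F31 * a01 + Fc$F32 * a02 + Fc$F33 * a03
    nv <- sqrt(v1^2 + v2^2 + v3^2)
    if (any(nv < 1e-12)) stop_numerical("fiber image has vanishing norm")
    A1 <- v1 / nv
    A2 <- v2 / nv
    A3 <- v3 / nv
  } else {
    one <- matrix(1, nrow(Fc$F11), ncol(Fc$F11))
    A1 <- a01 * one
    A2 <- a02 * one
    A3 <- a03 * one
  }
  # perpendicular frame: e2 ~ a x c with c the canonical axis least aligned
  # with a; e3 = a x e2. The tract measures are invariant to this choice.
  ab1 <- abs(A1)
  ab2 <- abs(A2)
  ab3 <- abs(A3)
  use_x <- (ab1 <= ab2) & (ab1 <= ab3)
  use_y <- !use_x & (ab2 <= ab3)
  use_z <- !use_x & !use_y
  # a x ex = (0, a3, -a2); a x ey = (-a3, 0, a1); a x ez = (a2, -a1, 0)
  c1 <- ifelse(use_x, 0, ifelse(use_y, -A3, A2))
  c2 <- ifelse(use_x, A3, ifelse(use_y, 0, -A1))
  c3 <- ifelse(use_x, -A2, ifelse(use_y, A1, 0))
  nc <- sqrt(c1^2 + c2^2 + c3^2)
  e21 <- c1 / nc
  e22 <- c2 / nc
  e23 <- c3 / nc
  e31 <- A2 * e23 - A3 * e22
  e32 <- A3 * e21 - A1 * e23
  e33 <- A1 * e22 - A2 * e21
  # u = E a ; w = E e2 ; z = E e3 (only needed projections)
  u1 <- E$E11 * A1 + E$E12 * A2 + E$E13 * A3
  u2 <- E$E12 * A1 + E$E22 * A2 + E$E23 * A3
  u3 <- E$E13 * A1 + E$E23 * A2 + E$E33 * A3
  Ep11 <- A1 * u1 + A2 * u2 + A3 * u3
  Ep12 <- e21 * u1 + e22 * u2 + e23 * u3
  Ep13 <- e31 * u1 + e32 * u2 + e33 * u3
  w1 <- E$E11 * e21 + E$E12 * e22 + E$E13 * e23
  w2 <- E$E12 * e21 + E$E22 * e22 + E$E23 * e23
  w3 <- E$E13 * e21 + E$E23 * e22 + E$E33 * e23
  Ep22 <- e21 * w1 + e22 * w2 + e23 * w3
  Ep23 <- e31 * w1 + e32 * w2 + e33 * w3
  z1 <- E$E11 * e31 + E$E12 * e32 + E$E13 * e33
  z2 <- E$E12 * e31 + E$E22 * e32 + E$E23 * e33
  z3 <- E$E13 * e31 + E$E23 * e32 + E$E33 * e33
  Ep33 <- e31 * z1 + e32 * z2 + e33 * z3
  mid <- (Ep22 + Ep33) / 2
  rad <- sqrt(((Ep22 - Ep33) / 2)^2 + Ep23^2)
  list(
    ton = Ep11,
    tpn = mid + rad,
    tos = sqrt(Ep12^2 + Ep13^2),
    tps = rad
  )
}

#' Tract-related strain histories for a single element
#'
#' At each time the Green-Lagrange tensor is rotated into an orthonormal
#' frame whose first axis is the (by default real-time, i.e. deformed) fiber
#' direction. The four measures are: the along-tract normal strain
#' (`ton`, signed), the peak normal strain perpendicular to the tract
#' (`tpn`, larger eigenvalue of the perpendicular 2x2 block), the shear
#' strain oriented along the tract (`tos`), and the peak shear strain
#' perpendicular to the tract (`tps`, half the difference of the
#' perpendicular principal strains). All four are invariant to the arbitrary
#' rotation of the perpendicular basis.
#'
#' Shear components are tensor (half-engineering) shears by default;
#' `engineering_shear = TRUE` doubles the two shear outputs.
#'
#' @param F_series `n_t x 3 x 3` array of deformation gradients.
#' @param a0 unit reference fiber vector.
#' @param realtime_fiber use the deformed fiber direction (`TRUE`, default)
#'   or the reference direction.
#' @param engineering_shear report engineering shear (2x tensor shear)?
#' @return tibble with columns `t_index, ton, tpn, tos, tps`.
#' @export
tract_strain_histories <- function(F_series, a0, realtime_fiber = TRUE,
                                   engineering_shear = FALSE) {
  if (any(!is.finite(a0)) || abs(sqrt(sum(a0^2)) - 1) > 1e-9) {
    stop_contract("tract strains need a unit fiber vector (white-matter elements only)")
  }
  n_t <- dim(F_series)[1]
  F4 <- array(F_series, c(1, n_t, 3, 3))
  Fc <- f_components(F4)
  E <- gl_components(Fc)
  h <- tract_components(Fc, E, matrix(a0, 1, 3), realtime = realtime_fiber)
  s <- if (engineering_shear) 2 else 1
  tibble(
    t_index = seq_len(n_t),
    ton = as.numeric(h$ton),
    tpn = as.numeric(h$tpn),
    tos = s * as.numeric(h$tos),
    tps = s * as.numeric(h$tps)
  )
}

#' Principal-strain history of one element
#'
#' Largest eigenvalue of the Green-Lagrange tensor at each time, plus its
#' running peak.
#'
#' @param F_series `n_t x 3 x 3` array of deformation gradients.
#' @return tibble `t_index, mps`, with the peak as attribute `"peak"`.
#' @export
mps_history <- function(F_series) {
  n_t <- dim(F_series)[1]
  F4 <- array(F_series, c(1, n_t, 3, 3))
  Fc <- f_components(F4)
  lam <- sym3_max_eig(gl_components(Fc))
  out <- tibble(t_index = seq_len(n_t), mps = as.numeric(lam))
  attr(out, "peak") <- max(out$mps)
  out
}

#' Per-element strain-peak table of a simulation
#'
#' Computes, for every element, the time-accumulated peak (max over the
#' simulation) of MPS, and for white-matter elements the four tract-related
#' strain peaks MTON, MTPN, MTOS, MTPS. The along-tract normal strain is
#' signed tension-positive; its accumulated peak is clamped at zero (the
#' undeformed start guarantees a zero baseline), so `mton <= mps` holds
#' element-wise. Elements whose deformation gradient loses positivity
#' (`det F <= 0` at any time) are flagged `valid = FALSE`, excluded from
#' summaries, and counted in the `"n_invalid"` attribute.
#'
#' @param sim a [strain_sim()].
#' @param realtime_fiber,engineering_shear see [tract_strain_histories()].
#' @return tibble `element_id, region, is_wm, valid, mps, mton, mtpn, mtos,
#'   mtps` (tract columns `NA` outside white matter).
#' @export
strain_peak_table <- function(sim, realtime_fiber = TRUE,
                              engineering_shear = FALSE) {
  Fc <- f_components(sim$F)
  detF <- det3_components(Fc)
  valid <- apply(detF > 0, 1, all)
  E <- gl_components(Fc)
  lam <- sym3_max_eig(E)
  mps_peak <- apply(lam, 1, max)
  n <- length(sim$element_id)
  out <- tibble(
    element_id = sim$element_id,
    region = sim$region,
    is_wm = is_white_matter(sim$region),
    valid = valid,
    mps = mps_peak,
    mton = NA_real_, mtpn = NA_real_, mtos = NA_real_, mtps = NA_real_
  )
  wm <- which(out$is_wm)
  if (length(wm) > 0) {
    Fw <- lapply(Fc, function(m) m[wm, , drop = FALSE])
    Ew <- lapply(E, function(m) m[wm, , drop = FALSE])
    h <- tract_components(Fw, Ew, sim$fiber[wm, , drop = FALSE],
      realtime = realtime_fiber
    )
    s <- if (engineering_shear) 2 else 1
    out$mton[wm] <- pmax(apply(h$ton, 1, max), 0)
    out$mtpn[wm] <- pmax(apply(h$tpn, 1, max), 0)
    out$mtos[wm] <- s * apply(h$tos, 1, max)
    out$mtps[wm] <- s * apply(h$tps, 1, max)
  }
  attr(out, "n_invalid") <- sum(!valid)
  attr(out, "helmet_id") <- sim$helmet_id
  attr(out, "location") <- sim$location
  out
}

strain_metric_cols <- function() {
  c(MPS = "mps", MTON = "mton", MTPN = "mtpn", MTOS = "mtos", MTPS = "mtps")
}

# rows of a peak table eligible for a given metric: whole brain for MPS,
# white matter for tract metrics; invalid elements always excluded.
eligible_rows <- function(table, metric) {
  metric <- match.arg(metric, names(strain_metric_cols()))
  ok <- table$valid
  if (metric != "MPS") ok <- ok & table$is_wm
  ok
}

#' Interpolated percentile of element peaks
#'
#' Linear interpolation between order statistics, i.e. the order statistic at
#' `k = 1 + q/100 * (n - 1)` (R's default quantile type 7).
#'
#' @param values numeric vector.
#' @param q percentile in `[0, 100]` (default 95).
#' @param mask optional logical mask selecting the eligible subset.
#' @return scalar percentile value.
#' @export
percentile_summary <- function(values, q = 95, mask = NULL) {
  if (!is.null(mask)) values <- values[mask]
  values <- values[is.finite(values)]
  if (length(values) == 0) stop_data("empty element set for percentile summary")
  unname(quantile(values, q / 100, type = 7))
}

#' Per-simulation strain summary
#'
#' The per-simulation percentile summary (default 95th) of each strain
#' metric over its eligible element set: whole brain for MPS, white matter
#' for the four tract metrics.
#'
#' @param peaks a [strain_peak_table()].
#' @param q percentile.
#' @return tibble `helmet_id, location, metric, value`.
#' @export
strain_summary <- function(peaks, q = 95) {
  cols <- strain_metric_cols()
  purrr::map_dfr(names(cols), function(metric) {
    tibble(
      helmet_id = attr(peaks, "helmet_id") %||% NA_character_,
      location = attr(peaks, "location") %||% NA_character_,
      metric = metric,
      value = percentile_summary(
        peaks[[cols[[metric]]]],
        q = q, mask = eligible_rows(peaks, metric)
      )
    )
  })
}

#' Restrict a peak table to one anatomical region
#'
#' @param table a [strain_peak_table()].
#' @param region a label from [strain_regions()].
#' @return the filtered peak table (metadata attributes preserved).
#' @export
region_restrict <- function(table, region) {
  if (!region %in% strain_regions()) {
    stop_parameter(sprintf(
      "unknown region '%s'; known: %s",
      region, paste(strain_regions(), collapse = ", ")
    ))
  }
  out <- table[table$region == region, , drop = FALSE]
  attr(out, "n_invalid") <- sum(!out$valid)
  attr(out, "helmet_id") <- attr(table, "helmet_id")
  attr(out, "location") <- attr(table, "location")
  out
}

# ---- text container I/O ---------------------------------------------------

#' Read/write a strain simulation as plain text
#'
#' A `strain_sim` is serialised to three delimited files under a common stem:
#' `<stem>_time.csv` (`step, t`), `<stem>_elements.csv`
#' (`element_id, region, fx, fy, fz`), and `<stem>_F.csv`
#' (`element_id, step, F11..F33`, row-major tensor components).
#'
#' @param sim a [strain_sim()].
#' @param stem path stem (no extension).
#' @return `write_strain_sim()` returns `stem` invisibly;
#'   `read_strain_sim()` returns a `strain_sim`.
#' @export
write_strain_sim <- function(sim, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    tibble(step = seq_along(sim$time), t = sim$time,
           helmet_id = sim$helmet_id, location = sim$location),
    paste0(stem, "_time.csv"), progress = FALSE
  )
  readr::write_csv(
    tibble(
      element_id = sim$element_id, region = sim$region,
      fx = sim$fiber[, 1], fy = sim$fiber[, 2], fz = sim$fiber[, 3]
    ),
    paste0(stem, "_elements.csv"), progress = FALSE
  )
  n_elem <- dim(sim$F)[1]
  n_t <- dim(sim$F)[2]
  Fdf <- tibble(
    element_id = rep(sim$element_id, each = n_t),
    step = rep(seq_len(n_t), times = n_elem)
  )
  for (i in 1:3) {
    for (j in 1:3) {
      # element-major, step within element
      Fdf[[sprintf("F%d%d", i, j)]] <- as.vector(t(sim$F[, , i, j]))
    }
  }
  readr::write_csv(Fdf, paste0(stem, "_F.csv"), progress = FALSE)
  invisible(stem)
}

#' @rdname write_strain_sim
#' @export
read_strain_sim <- function(stem) {
  tm <- readr::read_csv(paste0(stem, "_time.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  el <- readr::read_csv(paste0(stem, "_elements.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  Fdf <- readr::read_csv(paste0(stem, "_F.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  n_elem <- nrow(el)
  n_t <- nrow(tm)
  if (nrow(Fdf) != n_elem * n_t) {
    stop_format("deformation table has wrong number of rows")
  }
  Fdf <- Fdf[order(match(Fdf$element_id, el$element_id), Fdf$step), ]
  comp <- as.matrix(Fdf[paste0("F", c(11, 12, 13, 21, 22, 23, 31, 32, 33))])
  F <- array(NA_real_, c(n_elem, n_t, 3, 3))
  k <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      k <- k + 1
      F[, , i, j] <- matrix(comp[, k], n_elem, n_t, byrow = TRUE)
    }
  }
  strain_sim(
    F = F, time = tm$t, region = el$region,
    fiber = unname(as.matrix(el[c("fx", "fy", "fz")])),
    element_id = el$element_id,
    helmet_id = tm$helmet_id[1], location = tm$location[1]
  )
}
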