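#' Build a regular hexagonal (honeycomb) spring network
#'
#' Constructs a strip of \code{n_rows * n_cols} regular hexagonal cells (each
#' cell an alveolus in cross-section, each edge an alveolar wall) with uniform
#' wall rest length \code{l0}. Every wall is a tension-only linear spring;
#' every pair of walls meeting at a node is joined by a bond-bending spring
#' that resists changes of their mutual angle away from its initial value
#' (2*pi/3 in the regular honeycomb). The leftmost and rightmost node columns
#' form the grip boundaries for uniaxial stretching along x.
#'
#' @param n_rows,n_cols number of hexagonal cells vertically / horizontally
#'   (each >= 1; >= 2 recommended to suppress boundary effects).
#' @param l0 wall rest length (sets the length unit). Default 1.
#' @return An object of class \code{"hex_network"}: \code{nodes} (n x 2 matrix
#'   of reference positions), \code{springs} (data.frame \code{from, to, l0}),
#'   \code{triples} (data.frame \code{pivot, end1, end2, phi0} with the initial
#'   signed inter-wall angle), \code{left_boundary}, \code{right_boundary},
#'   \code{anchor} (node whose y is pinned to remove the rigid vertical
#'   translation), and cached sparse incidence matrices.
#' @examples
#' hx <- build_hex_lattice(1, 1)   # a single hexagon: 6 nodes, 6 walls
#' nrow(hx$springs)
#' @export
build_hex_lattice <- function(n_rows, n_cols, l0 = 1) {
  n_rows <- check_count(n_rows, "n_rows", lower = 1L)
  n_cols <- check_count(n_cols, "n_cols", lower = 1L)
  check_number(l0, "l0", lower = 0, strict_lower = TRUE)

  # vertex angles 30, 90, ... degrees: hexagons sit point-up, so each cell has
  # two vertical walls (perpendicular to the stretch axis, the ones that can
  # shorten and go flaccid) and four walls at +/-30 degrees to it
  ang <- pi / 6 + (0:5) * pi / 3
  vx_off <- l0 * cos(ang)
  vy_off <- l0 * sin(ang)

  centers <- expand.grid(i = seq_len(n_rows) - 1L, j = seq_len(n_cols) - 1L)
  cx <- sqrt(3) * l0 * centers$j + (centers$i %% 2L) * (sqrt(3) / 2 * l0)
  cy <- 1.5 * l0 * centers$i

  # all hexagon vertices, then dedupe shared ones by rounded coordinate key
  px <- as.vector(outer(vx_off, cx, `+`))
  py <- as.vector(outer(vy_off, cy, `+`))
  key <- paste(round(px / l0, 6), round(py / l0, 6))
  uniq <- !duplicated(key)
  node_of <- match(key, key[uniq])
  nodes <- cbind(x = px[uniq], y = py[uniq])
  nn <- nrow(nodes)

  # edges: consecutive vertices of each hexagon, deduped as undirected pairs
  n_hex <- length(cx)
  vid <- matrix(node_of, nrow = 6L)        # 6 x n_hex vertex node ids
  from <- as.vector(vid)
  to <- as.vector(vid[c(2:6, 1L), , drop = FALSE])
  lo <- pmin(from, to); hi <- pmax(from, to)
  ekey <- paste(lo, hi)
  keep <- !duplicated(ekey)
  springs <- data.frame(from = lo[keep], to = hi[keep], l0 = l0)

  # bond triples: every unordered pair of walls incident at a node
  inc <- split(rep(seq_len(nrow(springs)), 2L),
               c(springs$from, springs$to))
  trip <- list()
  for (p_chr in names(inc)) {
    es <- inc[[p_chr]]
    if (length(es) < 2L) next
    p <- as.integer(p_chr)
    prs <- utils::combn(es, 2L)
    other <- function(e) if (springs$from[e] == p) springs$to[e] else springs$from[e]
    for (c_i in seq_len(ncol(prs))) {
      e1 <- prs[1L, c_i]; e2 <- prs[2L, c_i]
      trip[[length(trip) + 1L]] <- c(p, other(e1), other(e2))
    }
  }
  trip <- do.call(rbind, trip)
  triples <- data.frame(pivot = trip[, 1L], end1 = trip[, 2L], end2 = trip[, 3L])
  ux <- nodes[triples$end1, 1L] - nodes[triples$pivot, 1L]
  uy <- nodes[triples$end1, 2L] - nodes[triples$pivot, 2L]
  vx <- nodes[triples$end2, 1L] - nodes[triples$pivot, 1L]
  vy <- nodes[triples$end2, 2L] - nodes[triples$pivot, 2L]
  triples$phi0 <- atan2(ux * vy - uy * vx, ux * vx + uy * vy)

  xr <- range(nodes[, 1L])
  left <- which(nodes[, 1L] < xr[1L] + 1e-6 * l0)
  right <- which(nodes[, 1L] > xr[2L] - 1e-6 * l0)
  anchor <- left[which.min(nodes[left, 2L])]

  ns <- nrow(springs); nt <- nrow(triples)
  net <- structure(list(
    nodes = nodes, springs = springs, triples = triples,
    left_boundary = left, right_boundary = right, anchor = anchor,
    # sparse incidence: spring vectors and the two arm vectors of each triple
    S  = Matrix::sparseMatrix(i = c(seq_len(ns), seq_len(ns)),
                              j = c(springs$to, springs$from),
                              x = rep(c(1, -1), each = ns), dims = c(ns, nn)),
    TU = Matrix::sparseMatrix(i = c(seq_len(nt), seq_len(nt)),
                              j = c(triples$end1, triples$pivot),
                              x = rep(c(1, -1), each = nt), dims = c(nt, nn)),
    TV = Matrix::sparseMatrix(i = c(seq_len(nt), seq_len(nt)),
                              j = c(triples$end2, triples$pivot),
                              x = rep(c(1, -1), each = nt), dims = c(nt, nn))
  ), class = "hex_network")
  net
}

#' @export
print.hex_network <- function(x, ...) {
  cat(sprintf("Hexagonal network: %d nodes, %d walls, %d bond triples\n",
              nrow(x$nodes), nrow(x$springs), nrow(x$triples)))
  invisible(x)
}

spring_geometry <- function(positions, network) {
  dx <- as.numeric(network$S %*% positions[, 1L])
  dy <- as.numeric(network$S %*% positions[, 2L])
  list(dx = dx, dy = dy, len = sqrt(dx^2 + dy^2))
}

#' Total elastic energy of a network configuration
#'
#' Sum of tension-only spring energies \code{0.5 * k * (l - l0)^2} over walls
#' longer than their rest length (shortened walls are flaccid and store
#' nothing) plus bond-bending energies \code{0.5 * b * (phi - phi0)^2} over
#' wall pairs, where \code{phi} is the current signed inter-wall angle at the
#' pivot node and \code{phi0} its initial value. Energy is invariant to rigid
#' translations and rotations; only the boundary constraints break the
#' invariance during stretching.
#'
#' @param positions n x 2 numeric matrix of node coordinates.
#' @param network a [build_hex_lattice] network.
#' @param k wall spring constant (force/length).
#' @param b bond-bending constant (energy/rad^2).
#' @return Total energy (scalar, >= 0).
#' @export
network_energy <- function(positions, network, k, b) {
  g <- spring_geometry(positions, network)
  if (any(g$len < 1e-12 * network$springs$l0))
    stopf("coincident nodes within a spring")
  ext <- pmax(g$len - network$springs$l0, 0)
  e_spring <- 0.5 * k * sum(ext^2)
  dphi <- triple_angle_dev(positions, network)
  e_spring + 0.5 * b * sum(dphi^2)
}

triple_angle_dev <- function(positions, network) {
  ux <- as.numeric(network$TU %*% positions[, 1L])
  uy <- as.numeric(network$TU %*% positions[, 2L])
  vx <- as.numeric(network$TV %*% positions[, 1L])
  vy <- as.numeric(network$TV %*% positions[, 2L])
  phi <- atan2(ux * vy - uy * vx, ux * vx + uy * vy)
  d <- phi - network$triples$phi0
  atan2(sin(d), cos(d))   # wrap to (-pi, pi]
}

# analytic gradient of network_energy w.r.t. node coordinates (n x 2 matrix)
network_gradient <- function(positions, network, k, b) {
  g <- spring_geometry(positions, network)
  ext <- pmax(g$len - network$springs$l0, 0)
  fmag <- k * ext / g$len
  gx <- as.numeric(Matrix::crossprod(network$S, fmag * g$dx))
  gy <- as.numeric(Matrix::crossprod(network$S, fmag * g$dy))

  if (b != 0) {
    ux <- as.numeric(network$TU %*% positions[, 1L])
    uy <- as.numeric(network$TU %*% positions[, 2L])
    vx <- as.numeric(network$TV %*% positions[, 1L])
    vy <- as.numeric(network$TV %*% positions[, 2L])
    ru2 <- ux^2 + uy^2
    rv2 <- vx^2 + vy^2
    phi <- atan2(ux * vy - uy * vx, ux * vx + uy * vy)
    d <- phi - network$triples$phi0
    m <- b * atan2(sin(d), cos(d))
    # d(phi)/d(u) = ( uy, -ux)/|u|^2 ; d(phi)/d(v) = (-vy,  vx)/|v|^2
    gx <- gx + as.numeric(Matrix::crossprod(network$TU, m * uy / ru2)) -
               as.numeric(Matrix::crossprod(network$TV, m * vy / rv2))
    gy <- gy - as.numeric(Matrix::crossprod(network$TU, m * ux / ru2)) +
               as.numeric(Matrix::crossprod(network$TV, m * vx / rv2))
  }
  out <- cbind(gx, gy)
  dimnames(out) <- NULL
  out
}

#' Quasi-static uniaxial stretch of a hexagonal network
#'
#' At each strain of the schedule, the right-boundary nodes are displaced
#' horizontally by \code{strain * L0} (L0 the reference strip length), the
#' left-boundary nodes are held horizontally in place, all nodes move freely
#' vertically (one left-corner node is pinned vertically to remove the rigid
#' translation mode), and the total network energy is minimized over all free
#' coordinates starting from the previous relaxed configuration (advanced
#' affinely to the new strain as a warm start). Minimization uses L-BFGS-B
#' with the analytic energy gradient; a step that fails to converge is retried
#' once from a slightly perturbed configuration and flagged if still
#' unsuccessful.
#'
#' Stress is the total horizontal force transmitted to the moving boundary
#' divided by the reference cross-section width (per unit depth), which by the
#' envelope theorem equals the derivative of minimized energy density with
#' respect to applied strain.
#'
#' @param network a [build_hex_lattice] network.
#' @param k wall spring constant.
#' @param b bond-bending constant. \code{b = 0} leaves the honeycomb
#'   mechanically unstable (zero-energy shear modes); a warning is issued and
#'   the result flagged.
#' @param strain_schedule strictly increasing strains starting at 0.
#' @param sample_strains strains (matched to nearest schedule entries) at
#'   which per-wall angles and strains are recorded. Default none.
#' @param control passed to \code{stats::optim} (L-BFGS-B); default
#'   \code{list(maxit = 2000, factr = 1e4)}.
#' @return An object of class \code{"network_curve_result"}: \code{curve}
#'   (a [stress_strain_curve] of network stress vs applied strain),
#'   \code{energy} per schedule strain, \code{samples} (data.frame
#'   \code{strain, wall_id, angle, wall_strain}), \code{flagged} (TRUE if any
#'   step failed to converge cleanly or b = 0), \code{positions} (final
#'   configuration), \code{k}, \code{b}.
#' @export
stretch_network <- function(network, k, b, strain_schedule,
                            sample_strains = NULL, control = NULL) {
  if (!inherits(network, "hex_network")) stopf("'network' must be a hex_network")
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  check_number(b, "b", lower = 0)
  if (strain_schedule[1L] != 0 || any(diff(strain_schedule) <= 0))
    stopf("strain_schedule must start at 0 and increase strictly")
  if (is.null(control)) control <- list(maxit = 2000L, factr = 1e4)
  flagged <- FALSE
  if (b == 0) {
    warning("b = 0: honeycomb is unstable (zero-energy shear modes); ",
            "results are unreliable", call. = FALSE)
    flagged <- TRUE
  }

  nodes0 <- network$nodes
  nn <- nrow(nodes0)
  xr <- range(nodes0[, 1L])
  l_strip <- diff(xr)
  w_strip <- diff(range(nodes0[, 2L]))

  fixed_x <- union(network$left_boundary, network$right_boundary)
  free_x <- setdiff(seq_len(nn), fixed_x)
  free_y <- setdiff(seq_len(nn), network$anchor)

  pos <- nodes0
  pack <- function(p) c(p[free_x, 1L], p[free_y, 2L])
  unpack <- function(z, p) {
    p[free_x, 1L] <- z[seq_along(free_x)]
    p[free_y, 2L] <- z[length(free_x) + seq_along(free_y)]
    p
  }

  n_step <- length(strain_schedule)
  energy <- numeric(n_step)
  stress <- numeric(n_step)
  samples <- list()
  sample_at <- if (is.null(sample_strains)) integer(0) else
    vapply(sample_strains, function(s) which.min(abs(strain_schedule - s)),
           integer(1))

  record_walls <- function(p, at) {
    g <- spring_geometry(p, network)
    data.frame(strain = at, wall_id = seq_len(nrow(network$springs)),
               angle = atan2(abs(g$dy), abs(g$dx)),
               wall_strain = (g$len - network$springs$l0) / network$springs$l0)
  }

  prev_strain <- 0
  for (s in seq_len(n_step)) {
    eps <- strain_schedule[s]
    if (eps > 0) {
      # affine warm start from the previous relaxed configuration
      pos[, 1L] <- xr[1L] + (pos[, 1L] - xr[1L]) * (1 + eps) / (1 + prev_strain)
      pos[network$left_boundary, 1L] <- nodes0[network$left_boundary, 1L]
      pos[network$right_boundary, 1L] <-
        nodes0[network$right_boundary, 1L] + eps * l_strip

      fn <- function(z) network_energy(unpack(z, pos), network, k, b)
      gr <- function(z) {
        gmat <- network_gradient(unpack(z, pos), network, k, b)
        c(gmat[free_x, 1L], gmat[free_y, 2L])
      }
      opt <- stats::optim(pack(pos), fn, gr, method = "L-BFGS-B",
                          control = control)
      if (opt$convergence != 0) {
        z2 <- pack(pos) + with_seed(s, stats::rnorm(length(pack(pos)),
                                                    sd = 1e-3 * mean(network$springs$l0)))
        opt2 <- stats::optim(z2, fn, gr, method = "L-BFGS-B", control = control)
        if (opt2$value <= opt$value) opt <- opt2
        if (opt$convergence != 0) flagged <- TRUE
      }
      pos <- unpack(opt$par, pos)
      energy[s] <- opt$value
    } else {
      energy[s] <- network_energy(pos, network, k, b)
    }
    gmat <- network_gradient(pos, network, k, b)
    stress[s] <- if (eps == 0) 0 else
      sum(gmat[network$right_boundary, 1L]) / w_strip
    if (s %in% sample_at)
      samples[[length(samples) + 1L]] <- record_walls(pos, eps)
    prev_strain <- eps
  }

  samples <- if (length(samples)) do.call(rbind, samples) else
    data.frame(strain = numeric(0), wall_id = integer(0), angle = numeric(0),
               wall_strain = numeric(0))
  structure(list(curve = stress_strain_curve(strain_schedule, stress),
                 energy = energy, samples = samples, flagged = flagged,
                 positions = pos, k = k, b = b,
                 strip_length = l_strip, strip_width = w_strip),
            class = "network_curve_result")
}

#' @export
print.network_curve_result <- function(x, ...) {
  cat(sprintf(
    "Network stretch: k = %g, b = %g, %d strains to %.3g, peak stress %.4g%s\n",
    x$k, x$b, nrow(x$curve), max(x$curve$strain), max(x$curve$stress),
    if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Theoretical analytical-model moduli implied by network parameters
#'
#' Equating the total elastic energies of the wall-ensemble model and the
#' hexagonal network gives the mapping \code{Y_ae = u * 9/(4 * l0_mean^2) * k}
#' and \code{Y_be = u * b / 8}, where \code{u} is a unity constant carrying
#' the dimensional conversion and \code{l0_mean} the mean initial wall length.
#'
#' @param k wall spring constant.
#' @param b bond-bending constant.
#' @param l0_mean mean initial wall length (default 1).
#' @param u unity conversion constant (default 1).
#' @return A [tissue_moduli] object.
#' @export
map_parameters <- function(k, b, l0_mean = 1, u = 1) {
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  check_number(b, "b", lower = 0, strict_lower = TRUE)
  check_number(l0_mean, "l0_mean", lower = 0, strict_lower = TRUE)
  tissue_moduli(u * 9 / (4 * l0_mean^2) * k, u * b / 8)
}

#' Validate the network-to-analytical parameter mapping
#'
#' For every combination of the spring-constant grid \code{k_grid} and
#' bending-constant grid \code{b_grid}: stretch the network quasi-statically
#' ([stretch_network]), fit the analytical wall-ensemble model to the
#' resulting stress-strain curve ([fit_moduli]), then regress the fitted
#' \code{Y_ae} on \code{k} at each fixed \code{b}, and the fitted \code{Y_be}
#' on \code{b} at each fixed \code{k}. Linearity of these relationships (high
#' adjusted r-squared) is the evidence that the analytical model recovers the
#' microscopic network parameters up to the theoretical proportionality
#' constants of [map_parameters].
#'
#' The analytical fits use the honeycomb initial-angle composition
#' (\code{angle_mode = "honeycomb"} in [simulation_config]): the
#' energy-equivalence argument behind the parameter mapping presumes the two
#' models describe the same wall population, and a regular hexagonal strip
#' has walls only at pi/6 and pi/2 to the stretch axis, not uniformly
#' distributed angles. Fits are run with \code{multistart = TRUE} because the
#' model only approximates the network curves and the SSE surface can hold
#' several shallow basins.
#'
#' @param k_grid,b_grid numeric grids (>= 3 values each). Defaults span one
#'   order of magnitude each, log-spaced, positioned so the implied
#'   tissue-level modulus ratio stays mostly inside the strain-stiffening
#'   regime of the network (b/k below about 0.1; larger bending constants
#'   make the network's response linear-to-concave and leave the bending
#'   modulus unidentifiable from the curve).
#' @param n_rows,n_cols lattice size in hexagons (default 8 x 8).
#' @param l0 wall rest length (default 1).
#' @param strain_schedule applied strains (default 0 to 0.6 in steps of
#'   0.025).
#' @param fit_config [simulation_config] for the analytical fits; default
#'   honeycomb angle composition (which has only two wall classes, so three
#'   walls represent it exactly) with strain increment 0.005.
#' @param verbose print progress lines.
#' @return An object of class \code{"mapping_validation"}: \code{fits}
#'   (data.frame \code{k, b, y_ae_fit, y_be_fit, y_ae_theory, y_be_theory,
#'   converged}), \code{regressions} (data.frame \code{response, fixed_param,
#'   fixed_value, slope, intercept, adj_r2}), \code{min_adj_r2},
#'   \code{theory_slopes} (the mapping constants 9/(4 l0^2) and 1/8).
#' @export
validate_mapping <- function(k_grid = c(1, sqrt(10), 10),
                             b_grid = c(0.01, 0.1 / sqrt(10), 0.1),
                             n_rows = 8L, n_cols = 8L, l0 = 1,
                             strain_schedule = seq(0, 0.6, by = 0.025),
                             fit_config = NULL, verbose = FALSE) {
  if (length(k_grid) < 3L || length(b_grid) < 3L)
    stopf("k_grid and b_grid each need at least 3 values for regression")
  if (is.null(fit_config))
    fit_config <- simulation_config(n_walls = 3L, d_eps = 0.005,
                                    max_strain = max(strain_schedule),
                                    angle_mode = "honeycomb")
  network <- build_hex_lattice(n_rows, n_cols, l0)
  grid <- expand.grid(k = k_grid, b = b_grid)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    k <- grid$k[i]; b <- grid$b[i]
    if (verbose)
      message(sprintf("stretch + fit %d/%d (k = %g, b = %g)", i, nrow(grid), k, b))
    row <- tryCatch({
      nc <- stretch_network(network, k, b, strain_schedule)
      fit <- fit_moduli(nc$curve, fit_config, multistart = TRUE)
      theory <- map_parameters(k, b, l0)
      data.frame(k = k, b = b,
                 y_ae_fit = fit$moduli$y_ae, y_be_fit = fit$moduli$y_be,
                 y_ae_theory = theory$y_ae, y_be_theory = theory$y_be,
                 converged = fit$converged)
    }, error = function(e) {
      warning(sprintf("fit failed at k = %g, b = %g: %s; excluded", k, b,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    res[[i]] <- row
  }
  fits <- do.call(rbind, res)

  regress <- function(df, y, x) {
    fit <- stats::lm(df[[y]] ~ df[[x]])
    c(slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      adj_r2 = summary(fit)$adj.r.squared)
  }
  regs <- list()
  for (bv in unique(fits$b)) {
    sub <- fits[fits$b == bv, ]
    if (nrow(sub) < 3L) next
    r <- regress(sub, "y_ae_fit", "k")
    regs[[length(regs) + 1L]] <- data.frame(
      response = "y_ae_vs_k", fixed_param = "b", fixed_value = bv,
      slope = r["slope"], intercept = r["intercept"], adj_r2 = r["adj_r2"])
  }
  for (kv in unique(fits$k)) {
    sub <- fits[fits$k == kv, ]
    if (nrow(sub) < 3L) next
    r <- regress(sub, "y_be_fit", "b")
    regs[[length(regs) + 1L]] <- data.frame(
      response = "y_be_vs_b", fixed_param = "k", fixed_value = kv,
      slope = r["slope"], intercept = r["intercept"], adj_r2 = r["adj_r2"])
  }
  regressions <- do.call(rbind, regs)
  rownames(regressions) <- NULL
  structure(list(fits = fits, regressions = regressions,
                 min_adj_r2 = min(regressions$adj_r2),
                 theory_slopes = c(y_ae_per_k = 9 / (4 * l0^2),
                                   y_be_per_b = 1 / 8)),
            class = "mapping_validation")
}

#' @export
print.mapping_validation <- function(x, ...) {
  cat(sprintf("Network-to-analytical mapping: %d (k, b) fits\n", nrow(x$fits)))
  print(x$regressions, row.names = FALSE)
  cat(sprintf("minimum adjusted r^2: %.4f\n", x$min_adj_r2))
  cat(sprintf("theoretical slopes: Y_ae/k = %.3f, Y_be/b = %.3f\n",
              x$theory_slopes[1L], x$theory_slopes[2L]))
  invisible(x)
}
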