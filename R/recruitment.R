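#' Sample a mixed population of myelinated vagal fibers
#'
#' Large motor A fibers and small parasympathetic B fibers with
#' truncated-normal diameters (mean at the interval center, SD a quarter of
#' the interval width, truncated at two SD), uniform positions in the nerve
#' cross-section, and uniform longitudinal node jitter in
#' `[-0.5, 0.5]` internodal lengths (INL; INL = 100 x diameter).
#'
#' @param n_a,n_b numbers of A and B fibers.
#' @param seed integer seed.
#' @param nerve_radius_um nerve cross-section radius, um.
#' @param a_range_um,b_range_um diameter intervals, um.
#' @return data.frame with `fiber_id`, `type`, `diameter`, `x`, `y`,
#'   `jitter`, `inl`.
#' @export
sample_population <- function(n_a = 1000, n_b = 1000, seed = 1,
                              nerve_radius_um = 90,
                              a_range_um = c(7, 11), b_range_um = c(2, 5)) {
  stopifnot(n_a >= 1, n_b >= 1)
  rtrunc <- function(n, range) {
    m <- mean(range); s <- diff(range) / 4
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(2 * n, m, s)
      out <- c(out, x[x >= range[1] & x <= range[2]])
    }
    out[seq_len(n)]
  }
  .with_seed(seed, {
    n <- n_a + n_b
    d <- c(rtrunc(n_a, a_range_um), rtrunc(n_b, b_range_um))
    r <- nerve_radius_um * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    data.frame(fiber_id = seq_len(n),
               type = rep(c("A", "B"), c(n_a, n_b)),
               diameter = d, x = r * cos(th), y = r * sin(th),
               jitter = stats::runif(n, -0.5, 0.5),
               inl = 100 * d, stringsAsFactors = FALSE)
  })
}

#' Bipolar cuff electrode geometry in a homogeneous medium
#'
#' Two annular band contacts on the cuff inner surface (just outside the
#' nerve), separated longitudinally by the center-to-center spacing, in an
#' isotropic volume conductor.  Each band is discretized into a grid of
#' equal-current point sources around the ring and across the contact
#' width; `n_ring = 1` with zero width reduces to a single point source per
#' contact.  The cathode leads distally by default.
#'
#' @param spacing_um center-to-center contact spacing, um.
#' @param standoff_um radial gap between nerve surface and cuff, um.
#' @param nerve_radius_um nerve radius, um.
#' @param sigma_s_m medium conductivity, S/m.
#' @param n_ring azimuthal discretization points per band.
#' @param contact_width_um axial extent of each band.
#' @param n_axial axial discretization points per band.
#' @return list with contact centers (`cathode`, `anode`; x, y, z in um),
#'   sub-source matrices (`cathode_pts`, `anode_pts`) and `sigma_s_m`.
#' @export
electrode_geometry <- function(spacing_um = 895, standoff_um = 10,
                               nerve_radius_um = 90, sigma_s_m = 0.3,
                               n_ring = 12, contact_width_um = 200,
                               n_axial = 3) {
  r <- nerve_radius_um + standoff_um
  band <- function(zc) {
    th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
    zs <- if (n_axial > 1)
      zc + seq(-0.5, 0.5, length.out = n_axial) * contact_width_um
    else zc
    g <- expand.grid(th = th, z = zs)
    cbind(x = r * cos(g$th), y = r * sin(g$th), z = g$z)
  }
  list(cathode = c(x = r, y = 0, z = -spacing_um / 2),
       anode = c(x = r, y = 0, z = spacing_um / 2),
       cathode_pts = band(-spacing_um / 2),
       anode_pts = band(spacing_um / 2),
       sigma_s_m = sigma_s_m)
}

#' Extracellular potentials of the bipolar band-contact pair
#'
#' Superposed point sources, `V(r) = sum_k I_k / (4 pi sigma |r - r_k|)`,
#' with the total current `-I` spread over the cathode band's sub-sources
#' and `+I` over the anode's (first, cathodic phase).  Distances below 1 um
#' are clamped with a warning.
#'
#' @param geometry an [electrode_geometry()].
#' @param current_ma stimulus current, mA.
#' @param nodes numeric matrix (n x 3) of node coordinates, um.
#' @return potentials in volts at each node.
#' @export
extracellular_potential <- function(geometry, current_ma, nodes) {
  nodes <- matrix(as.numeric(nodes), ncol = 3)
  mean_inv_dist <- function(pts) {
    pts <- matrix(as.numeric(pts), ncol = 3)
    inv <- vapply(seq_len(nrow(pts)), function(k) {
      d <- sqrt((nodes[, 1] - pts[k, 1])^2 + (nodes[, 2] - pts[k, 2])^2 +
                (nodes[, 3] - pts[k, 3])^2)
      if (any(d < 1)) {
        warning("node within 1 um of a contact; distance clamped")
        d <- pmax(d, 1)
      }
      1 / d
    }, numeric(nrow(nodes)))
    rowMeans(matrix(inv, nrow = nrow(nodes)))
  }
  # I [mA] / (4 pi sigma [S/m] r [um]) = 1e3 * I / (4 pi sigma r) volts
  k <- 1e3 * current_ma / (4 * pi * geometry$sigma_s_m)
  k * (mean_inv_dist(geometry$anode_pts) - mean_inv_dist(geometry$cathode_pts))
}

# node coordinates of a fiber (21 nodes, centered between the contacts,
# shifted by jitter x INL)
.fiber_nodes <- function(fiber, n_nodes = 21) {
  z <- ((seq_len(n_nodes) - 1) - (n_nodes - 1) / 2 + fiber$jitter) * fiber$inl
  cbind(x = rep(fiber$x, n_nodes), y = rep(fiber$y, n_nodes), z = z)
}

#' Activation threshold of one fiber by bisection
#'
#' The fiber is a reduced myelinated cable: 21 Hodgkin-Huxley-style active
#' nodes of Ranvier joined by passive internodal resistances, with the
#' extracellular potentials of the biphasic pulse applied through the
#' activating-function term.  The threshold is the smallest amplitude (1%
#' bisection tolerance, 10 mA upper bound) that elicits an action potential
#' (membrane potential crossing -30 mV with a rising edge) detected at 90%
#' of the fiber length; `Inf` flags fibers not activated at the bound.
#'
#' @param fiber one row of [sample_population()].
#' @param geometry an [electrode_geometry()].
#' @param phase_us phase width of the biphasic pulse, us.
#' @param n_nodes number of nodes of Ranvier.
#' @param upper_ma bisection upper bound, mA.
#' @param tol relative bisection tolerance.
#' @param dt_ms integration step, ms.
#' @param sim_ms simulated time, ms (covers propagation to the detector).
#' @return threshold current in mA (possibly `Inf`).
#' @export
find_threshold <- function(fiber, geometry = electrode_geometry(),
                           phase_us = 300, n_nodes = 21, upper_ma = 10,
                           tol = 0.01, dt_ms = 0.002, sim_ms = 6) {
  nodes <- .fiber_nodes(fiber, n_nodes)
  ve_mv <- 1000 * extracellular_potential(geometry, 1, nodes)
  d <- fiber$diameter
  area_cm2 <- pi * (0.7 * d * 1e-4) * 1e-4        # 0.7D x 1 um node
  c_node_uf <- 1 * area_cm2                        # 1 uF/cm^2
  g_ax_ms <- 1000 * (pi * (0.6 * d * 1e-4)^2 / 4) / (70 * fiber$inl * 1e-4)
  detect_node <- floor(0.9 * (n_nodes - 1))
  .fiber_threshold_c(ve_mv, phase_us / 1000, g_ax_ms, c_node_uf, area_cm2,
                     sim_ms, dt_ms, detect_node, 3, upper_ma, tol)
}

#' Does a fiber fire at a given stimulus amplitude?
#'
#' Direct simulation of the reduced cable at one amplitude; used to verify
#' that a returned threshold brackets activation (no spike just below it, a
#' spike just above it).
#'
#' @inheritParams find_threshold
#' @param amplitude_ma stimulus amplitude, mA.
#' @return logical.
#' @export
fiber_fires <- function(fiber, amplitude_ma, geometry = electrode_geometry(),
                        phase_us = 300, n_nodes = 21, dt_ms = 0.002,
                        sim_ms = 6) {
  nodes <- .fiber_nodes(fiber, n_nodes)
  ve_mv <- 1000 * extracellular_potential(geometry, 1, nodes)
  d <- fiber$diameter
  area_cm2 <- pi * (0.7 * d * 1e-4) * 1e-4
  g_ax_ms <- 1000 * (pi * (0.6 * d * 1e-4)^2 / 4) / (70 * fiber$inl * 1e-4)
  detect_node <- floor(0.9 * (n_nodes - 1))
  .fiber_fires_c(ve_mv, amplitude_ma, phase_us / 1000, g_ax_ms, area_cm2,
                 area_cm2, sim_ms, dt_ms, detect_node, 3)
}

#' Thresholds for a whole fiber population
#'
#' @param population data.frame from [sample_population()].
#' @param ... passed to [find_threshold()].
#' @return the population with a `threshold_ma` column appended.
#' @export
population_thresholds <- function(population, ...) {
  population$threshold_ma <- vapply(seq_len(nrow(population)), function(i)
    find_threshold(population[i, ], ...), numeric(1))
  population
}

#' Recruitment curves by fiber type
#'
#' Cumulative fraction of fibers of each type with threshold at or below
#' each amplitude.
#'
#' @param population data.frame with `type` and `threshold_ma` columns.
#' @param amplitudes_ma amplitude grid, mA.
#' @return data.frame with `amplitude_ma`, `type`, `fraction`.
#' @export
recruitment_curves <- function(population, amplitudes_ma) {
  out <- expand.grid(amplitude_ma = amplitudes_ma,
                     type = unique(population$type),
                     stringsAsFactors = FALSE)
  out$fraction <- mapply(function(a, ty) {
    thr <- population$threshold_ma[population$type == ty]
    mean(thr <= a)
  }, out$amplitude_ma, out$type)
  out
}

#' Perineurium thickness from fascicle diameter
#'
#' Published linear fit `0.01292 * d_fasc + 1.367` (um); a documented helper
#' unused by the homogeneous-medium field model.
#'
#' @param d_fasc_um fascicle diameter, um (>= 0).
#' @return perineurium thickness, um.
#' @export
perineurium_thickness <- function(d_fasc_um) {
  if (any(d_fasc_um < 0)) stop("fascicle diameter must be non-negative")
  0.01292 * d_fasc_um + 1.367
}
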