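# Independent numerical oracles and small fixture builders.

# random valid geometry with angulations spread over the sphere
random_geometry <- function() {
  sod <- runif(1, 600, 900)
  CArmGeometry(sid_mm = sod * runif(1, 1.2, 2), sod_mm = sod,
               primary_deg = runif(1, -90, 90),
               secondary_deg = runif(1, -45, 45),
               label = "rand")
}

random_line <- function() {
  ProjectionLine(origin = runif(3, -500, 500), direction = rnorm(3))
}

# brute-force closest approach of two lines: 2-parameter numerical
# minimization of the squared distance (independent of the normal
# equations used by the implementation)
bf_closest_lines <- function(a, b) {
  f <- function(par) {
    pa <- a@origin + par[1] * a@direction
    pb <- b@origin + par[2] * b@direction
    sum((pa - pb)^2)
  }
  fit <- stats::optim(c(0, 0), f, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  pa <- a@origin + fit$par[1] * a@direction
  pb <- b@origin + fit$par[2] * b@direction
  list(nadir_a = pa, nadir_b = pb, gap = sqrt(fit$value))
}

# independent closed form for the gap only: |r . (d1 x d2)| / |d1 x d2|
cross_gap <- function(a, b) {
  d1 <- a@direction; d2 <- b@direction
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  abs(sum((b@origin - a@origin) * cr)) / sqrt(sum(cr^2))
}

# 1-D brute-force point-to-line distance
bf_point_line <- function(line, q) {
  f <- function(t) sum((line@origin + t * line@direction - q)^2)
  span <- sqrt(sum((q - line@origin)^2)) + 10
  sqrt(stats::optimize(f, c(-2 * span, 2 * span), tol = 1e-10)$objective)
}

# a minimal run with prescribed times, marker track and diaphragm trace
make_run <- function(t_s, peaks, diaphragm_mm, u = 0, v = 0, fps = 15,
                     geom = CArmGeometry(label = "AP")) {
  XRRun(data.frame(frame = seq_along(t_s) - 1L, t_s = t_s,
                   marker_u_mm = rep_len(u, length(t_s)),
                   marker_v_mm = rep_len(v, length(t_s)),
                   diaphragm_mm = diaphragm_mm),
        peaks, fps, geom)
}

ap_lao60 <- function() list(CArmGeometry(label = "AP"),
                            CArmGeometry(label = "LAO60", primary_deg = 60))

# motion parameters for a marker at rest (surrogate still breathing)
static_motion <- function(seed = 1, detector_noise = 0, trace_noise = 0) {
  motionParams(cardiac_amp = c(0, 0, 0), resp_amp = c(0, 0, 0),
               rr_sd_s = 0, detector_noise_sd_mm = detector_noise,
               trace_noise_sd_mm = trace_noise, seed = seed)
}
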