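# Region classification of the (alpha, T) / (nu, alpha) parameter space:
#   HC  highly correlated retrieval (|m| >= theta_hc; retrieval is preferred
#       whenever it exists alongside spin-glass order)
#   WC  weakly correlated retrieval (0 < |m| < theta_wc; arises only in the
#       one-set AM system, where the overlap can decay continuously)
#   SG  no retrieval, nonzero spin-glass order
#   TS  only the trivial solution
#   IND retrieval exists with theta_wc <= |m| < theta_hc: the indeterminate
#       band between the two thresholds, reported explicitly rather than
#       silently binned
#   ERR the solver failed (divergence) at that cell

#' Classify one parameter-space point
#'
#' Solves the retrieval and spin-glass branches at `ctx` and assigns the
#' region label (see the codes above).  Retrieval with `|m| >= theta_hc`
#' wins over spin-glass order; anti-pattern retrieval (`m <= -theta_hc`)
#' counts as HC, since specular copies are retrieved states too.
#'
#' @param ctx an [mf_context()].
#' @param theta_hc,theta_wc overlap thresholds, `0 < theta_wc <= theta_hc < 1`.
#'   `theta_wc = 0.5` corresponds to at most 75% of neurons correct.
#' @param ... passed to [solve_branch()].
#' @return A list: `label` (one of `"HC"`, `"WC"`, `"SG"`, `"TS"`, `"IND"`,
#'   `"ERR"`), `m` (retrieval overlap or `NA`), `retrieval`, `spin_glass`
#'   (the two branch results).
#' @export
classify_point <- function(ctx, theta_hc = 0.9, theta_wc = 0.5, ...) {
  if (!(theta_wc > 0 && theta_wc <= theta_hc && theta_hc < 1))
    stop("thresholds must satisfy 0 < theta_wc <= theta_hc < 1")
  ret <- solve_branch(ctx, "retrieval", ...)
  sg <- if (ctx$alpha > 0) solve_branch(ctx, "spin_glass", ...)
        else list(status = "no_solution")
  if (ret$status == "diverged" || identical(sg$status, "diverged"))
    return(list(label = "ERR", m = NA_real_, retrieval = ret, spin_glass = sg))
  if (ret$status == "converged") {
    am <- abs(ret$op$m)
    wc_allowed <- ctx$dynamics == "AM" && ctx$variant == "one_set"
    label <- if (am >= theta_hc) "HC"
             else if (am < theta_wc && wc_allowed) "WC"
             else "IND"
    return(list(label = label, m = ret$op$m, retrieval = ret, spin_glass = sg))
  }
  label <- if (identical(sg$status, "converged")) "SG" else "TS"
  list(label = label, m = NA_real_, retrieval = ret, spin_glass = sg)
}

#' Phase diagram over a load/temperature grid
#'
#' Classifies every `(alpha, T)` cell of a grid at fixed `nu` with
#' [classify_point()].  Solver failures label their cell `"ERR"` instead of
#' aborting the sweep.
#'
#' @param dynamics,variant,nu system selectors (see [mf_context()]).
#' @param alpha_grid,t_grid strictly increasing numeric grids.
#' @param theta_hc,theta_wc thresholds passed to [classify_point()].
#' @param out optional CSV path (written via [write_results()]).
#' @param ... passed to [solve_branch()].
#' @return A `data.frame` with columns `alpha`, `temperature`, `region`,
#'   `m`.
#' @export
phase_diagram <- function(dynamics, variant, nu,
                          alpha_grid = seq(0.002, 0.35, length.out = 41),
                          t_grid = seq(0, 1.5, length.out = 41),
                          theta_hc = 0.9, theta_wc = 0.5, out = NULL, ...) {
  if (is.unsorted(alpha_grid, strictly = TRUE) ||
      is.unsorted(t_grid, strictly = TRUE))
    stop("grids must be strictly increasing")
  cells <- expand.grid(alpha = alpha_grid, temperature = t_grid,
                       KEEP.OUT.ATTRS = FALSE)
  lab <- character(nrow(cells)); mv <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ctx <- mf_context(cells$alpha[i], nu, cells$temperature[i], dynamics, variant)
    cl <- tryCatch(classify_point(ctx, theta_hc, theta_wc, ...),
                   error = function(e) list(label = "ERR", m = NA_real_))
    lab[i] <- cl$label; mv[i] <- if (is.null(cl$m)) NA_real_ else cl$m
  }
  res <- data.frame(alpha = cells$alpha, temperature = cells$temperature,
                    region = lab, m = mv)
  if (!is.null(out))
    write_results(res, out, metadata = list(command = "phase_diagram",
                                            dynamics = dynamics,
                                            variant = variant, nu = nu))
  res
}

#' Coexistence map of AM and SPR retrieval in the (nu, alpha) plane
#'
#' Computes, at fixed temperature, where the AM dynamics and the SPR
#' dynamics each have highly correlated retrieval (`HC`), and their
#' intersection.  In the two-set model the intersection is non-empty over
#' an interval of `nu` (fixed-point and cyclic attractors coexist); in the
#' one-set model it is empty at every temperature.
#'
#' @param variant `"one_set"` or `"two_set"`.
#' @param temperature dynamics temperature (0 uses the zero-T equations).
#' @param nu_grid,alpha_grid grids over the mixture and the load.
#' @param theta_hc HC threshold on the retrieval overlap.
#' @param out optional CSV path.
#' @param ... passed to [solve_branch()].
#' @return A `data.frame` with columns `nu`, `alpha`, `am_hc`, `spr_hc`,
#'   `both` (logicals), with attribute `nonempty` (is any cell `both`?).
#' @export
coexistence_map <- function(variant, temperature = 0,
                            nu_grid = seq(0, 1, length.out = 41),
                            alpha_grid = seq(0.002, 0.3, length.out = 41),
                            theta_hc = 0.9, out = NULL, ...) {
  hc_at <- function(dynamics, nu, alpha) {
    ctx <- mf_context(alpha, nu, temperature, dynamics, variant)
    ret <- tryCatch(solve_branch(ctx, "retrieval", ...),
                    error = function(e) list(status = "error"))
    ret$status == "converged" && abs(ret$op$m) >= theta_hc
  }
  cells <- expand.grid(nu = nu_grid, alpha = alpha_grid, KEEP.OUT.ATTRS = FALSE)
  am <- logical(nrow(cells)); spr <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    am[i] <- hc_at("AM", cells$nu[i], cells$alpha[i])
    spr[i] <- hc_at("SPR", cells$nu[i], cells$alpha[i])
  }
  res <- data.frame(nu = cells$nu, alpha = cells$alpha,
                    am_hc = am, spr_hc = spr, both = am & spr)
  attr(res, "nonempty") <- any(res$both)
  if (!is.null(out))
    write_results(res, out, metadata = list(command = "coexistence_map",
                                            variant = variant,
                                            temperature = temperature))
  res
}
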