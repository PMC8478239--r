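DDG_CONST <- 4.0963   # makes the wild-type rate ratio k_f/k_u = 1000 map to ~0
DDG_SLOPE <- 0.593    # kcal/mol per natural-log unit of k_f/k_u

#' Rate constants for the ER folding/export model
#'
#' Defaults are the reference parameterization: production `P = 0.1`,
#' degradation of unfolded protein `k_p = 10`, wild-type folding
#' `k_f = 10` and unfolding `k_u = 0.01`, export `k_out = 0.01`, and
#' chaperone binding/dissociation `kon_L = 0.1`, `k_off = 0.01` when the
#' chaperone is present or `1e-5` for both when it is absent
#' (`chaperone = FALSE`). Rates are in arbitrary inverse-time units;
#' only their ratios matter for the steady state.
#'
#' @param production,k_p,k_f,k_u,kon_L,k_off,k_out numeric rates.
#' @param chaperone logical; when FALSE and `kon_L`/`k_off` are not given,
#'   both default to `1e-5`.
#' @return a [KineticParams-class].
#' @export
kineticParams <- function(production = 0.1, k_p = 10, k_f = 10, k_u = 0.01,
                          kon_L = NULL, k_off = NULL, k_out = 0.01,
                          chaperone = TRUE) {
  if (is.null(kon_L)) kon_L <- if (chaperone) 0.1 else 1e-5
  if (is.null(k_off)) k_off <- if (chaperone) 0.01 else 1e-5
  new("KineticParams", production = production, k_p = k_p, k_f = k_f,
      k_u = k_u, kon_L = kon_L, k_off = k_off, k_out = k_out)
}

#' Closed-form steady state of the ER folding/export scheme
#'
#' Solves `dU/dt = P - k_p U - k_f U + k_u F = 0`,
#' `dF/dt = k_f U - (k_u + kon_L + k_out) F + k_off F_B = 0`,
#' `dFB/dt = kon_L F - (k_off + k_out) F_B = 0` in closed form. The bound
#' state satisfies `F_B = kon_L F / (k_off + k_out)` and the folded state
#' `F = k_f P / ((k_p + k_f) A - k_f k_u)` with
#' `A = k_u + kon_L + k_out - k_off kon_L / (k_off + k_out)`.
#' The export flux is `dEdt = k_out (F + F_B)`; at steady state the mass
#' balance `P = k_p U + dEdt` holds.
#'
#' @param params a [KineticParams-class].
#' @return list with `U`, `F`, `F_B`, `dEdt`.
#' @examples
#' steadyState(kineticParams())                       # with chaperone
#' steadyState(kineticParams(chaperone = FALSE))
#' @export
steadyState <- function(params) {
  stopifnot(is(params, "KineticParams"))
  P <- params@production; kp <- params@k_p; kf <- params@k_f
  ku <- params@k_u; kon <- params@kon_L; koff <- params@k_off
  kout <- params@k_out
  if (P == 0) return(list(U = 0, F = 0, F_B = 0, dEdt = 0))
  bdenom <- koff + kout
  if (kon > 0 && bdenom == 0)
    stop("kon_L > 0 with k_off + k_out = 0: bound state has no sink")
  bound_ratio <- if (kon == 0) 0 else kon / bdenom
  A <- ku + kon + kout - koff * bound_ratio
  denom <- (kp + kf) * A - kf * ku
  if (denom <= 0)
    stop("degenerate rate combination: steady-state denominator <= 0")
  Fst <- kf * P / denom
  FB <- bound_ratio * Fst
  U <- (P + ku * Fst) / (kp + kf)
  list(U = U, F = Fst, F_B = FB, dEdt = kout * (Fst + FB))
}

#' Numerically integrate the folding/export ODE system
#'
#' Integrates the four-species system (U, F, F_B and the cumulative
#' exported amount E) with `deSolve::lsoda`; used as the independent
#' oracle for [steadyState()].
#'
#' @param params a [KineticParams-class].
#' @param t_end final time.
#' @param init named numeric initial state `c(U=, F=, F_B=, E=)`.
#' @param n_steps number of output time points.
#' @return matrix with columns `time`, `U`, `F`, `F_B`, `E`.
#' @export
integrateODEs <- function(params, t_end = 1e4,
                          init = c(U = 0, F = 0, F_B = 0, E = 0),
                          n_steps = 200L) {
  stopifnot(is(params, "KineticParams"), t_end > 0)
  deriv <- function(t, y, p) {
    with(as.list(y), {
      dU <- p@production - p@k_p * U - p@k_f * U + p@k_u * F
      dF <- p@k_f * U - (p@k_u + p@kon_L + p@k_out) * F + p@k_off * F_B
      dFB <- p@kon_L * F - (p@k_off + p@k_out) * F_B
      dE <- p@k_out * (F + F_B)
      list(c(dU, dF, dFB, dE))
    })
  }
  times <- seq(0, t_end, length.out = n_steps)
  out <- deSolve::lsoda(init, times, deriv, params,
                        rtol = 1e-10, atol = 1e-12)
  if (attr(out, "istate")[1] < 0) stop("ODE solver failed to converge")
  unclass(out)
}

#' Map a stability change to folding/unfolding rates
#'
#' Under a two-state model the stability change of a mutation relates to
#' the rate ratio via `ddg = 4.0963 - 0.593 * ln(k_f / k_u)`; the constant
#' makes the wild-type rates (`k_f = 10`, `k_u = 0.01`) correspond to
#' `ddg ~ 0`. A mutation is modelled as perturbing exactly one rate:
#' `mode = "unfolding"` (phi = 0, late-folding residue) holds `k_f` at the
#' wild-type value and solves for `k_u`; `mode = "folding"` (phi = 1,
#' early-folding residue) holds `k_u` and solves for `k_f`.
#'
#' @param ddg stability change in kcal/mol (positive destabilizes).
#' @param mode `"unfolding"` or `"folding"`.
#' @param wt_kf,wt_ku wild-type rates.
#' @param warn_range warn when the resulting rate leaves the reference
#'   sweep ranges (`k_u` in \\[0.005, 10\\], `k_f` in \\[0.01, 20\\]).
#' @return named numeric `c(k_f =, k_u =)`.
#' @seealso [ddgFromRates()] for the inverse map.
#' @export
ratesFromDdg <- function(ddg, mode = c("unfolding", "folding"),
                         wt_kf = 10, wt_ku = 0.01, warn_range = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.finite(ddg))
  ratio <- exp((DDG_CONST - ddg) / DDG_SLOPE)  # k_f / k_u
  if (mode == "unfolding") {
    kf <- wt_kf
    ku <- wt_kf / ratio
    if (warn_range && (ku < 0.005 || ku > 10))
      warning("k_u = ", signif(ku, 3), " outside reference sweep [0.005, 10]")
  } else {
    ku <- wt_ku
    kf <- wt_ku * ratio
    if (warn_range && (kf < 0.01 || kf > 20))
      warning("k_f = ", signif(kf, 3), " outside reference sweep [0.01, 20]")
  }
  c(k_f = kf, k_u = ku)
}

#' @rdname ratesFromDdg
#' @param k_f,k_u folding and unfolding rates.
#' @export
ddgFromRates <- function(k_f, k_u) {
  DDG_CONST - DDG_SLOPE * log(k_f / k_u)
}

#' Wild-type reference stability change
#'
#' The `ddg` value implied by the wild-type rates; approximately zero by
#' construction of the constant 4.0963.
#'
#' @inheritParams ratesFromDdg
#' @export
wildTypeDdg <- function(wt_kf = 10, wt_ku = 0.01) ddgFromRates(wt_kf, wt_ku)

#' Chaperone-rescue curve: export flux versus stability change
#'
#' For each `ddg` on the grid, maps the stability change to rates in the
#' requested mode, solves the steady state with or without chaperone, and
#' reports the export flux. Comparing the two modes quantifies why
#' destabilization through faster unfolding (late-folding residues, few
#' inverse-parallel relations) is easier to rescue with a folded-state
#' binder than equivalent destabilization through slower folding.
#'
#' @param ddg_grid numeric vector of stability changes (kcal/mol).
#' @param mode `"unfolding"` or `"folding"`; see [ratesFromDdg()].
#' @param chaperone logical, chaperone present.
#' @param base a [KineticParams-class] supplying the non-folding rates.
#' @return data.frame with columns `ddg`, `mode`, `chaperone`, `k_f`,
#'   `k_u`, `dEdt`.
#' @examples
#' rescueCurve(seq(0, 3, by = 0.5), mode = "unfolding", chaperone = TRUE)
#' @export
rescueCurve <- function(ddg_grid, mode = c("unfolding", "folding"),
                        chaperone = TRUE,
                        base = kineticParams(chaperone = chaperone)) {
  mode <- match.arg(mode)
  out <- data.frame(ddg = as.numeric(ddg_grid), mode = mode,
                    chaperone = chaperone, k_f = NA_real_, k_u = NA_real_,
                    dEdt = NA_real_)
  for (k in seq_len(nrow(out))) {
    r <- ratesFromDdg(out$ddg[k], mode, warn_range = FALSE)
    p <- new("KineticParams", production = base@production, k_p = base@k_p,
             k_f = unname(r["k_f"]), k_u = unname(r["k_u"]),
             kon_L = base@kon_L, k_off = base@k_off, k_out = base@k_out)
    out$k_f[k] <- r["k_f"]
    out$k_u[k] <- r["k_u"]
    out$dEdt[k] <- steadyState(p)$dEdt
  }
  out
}
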