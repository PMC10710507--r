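#' Microscopic rate constants for a three-state binding scheme
#'
#' Bundles the four microscopic rate constants of a three-state
#' receptor-ligand binding scheme together with the scheme identity.
#' Two schemes are supported:
#'
#' * induced fit (`"IF"`): R1 + L <-> R1L <-> R2L, i.e. the ligand binds the
#'   ground conformation first and the conformational change follows binding;
#' * conformational selection (`"CS"`): R1 <-> R2, R2 + L <-> R2L, i.e. the
#'   conformational change precedes binding.
#'
#' `k_e` and `k_r` are the conformational excitation and relaxation rate
#' constants between the two receptor conformations; `k_plus` and `k_minus`
#' are the bimolecular association and unimolecular dissociation rate
#' constants of the binding step. All internal units are SI: molar and
#' seconds (`k_plus` in /M/s, the others in /s).
#'
#' @param model `"IF"` or `"CS"`.
#' @param k_plus Bimolecular association rate constant (/M/s).
#' @param k_minus Dissociation rate constant (/s).
#' @param k_e Conformational excitation rate constant (/s).
#' @param k_r Conformational relaxation rate constant (/s).
#' @return An object of class `mechanism_params`.
#' @examples
#' p <- mechanism_params("IF", k_plus = 9.009e5, k_minus = 0.6,
#'                       k_e = 0.01, k_r = 1.1)
#' overall_kd(p)
#' @export
mechanism_params <- function(model = c("IF", "CS"), k_plus, k_minus, k_e, k_r) {
  model <- match.arg(model)
  rates <- c(k_plus = k_plus, k_minus = k_minus, k_e = k_e, k_r = k_r)
  if (!all(is.finite(rates)) || any(rates < 0)) {
    stop("all rate constants must be finite and >= 0; got ",
         paste(sprintf("%s=%g", names(rates), rates), collapse = ", "))
  }
  if (model == "IF" && k_e + k_r <= 0) {
    stop("induced-fit scheme requires k_e + k_r > 0")
  }
  if (model == "CS" && k_e <= 0) {
    stop("conformational-selection scheme requires k_e > 0")
  }
  structure(list(model = model, k_plus = k_plus, k_minus = k_minus,
                 k_e = k_e, k_r = k_r),
            class = "mechanism_params")
}

#' @export
print.mechanism_params <- function(x, ...) {
  cat(sprintf("<%s mechanism> k+ = %g /M/s, k- = %g /s, k_e = %g /s, k_r = %g /s\n",
              x$model, x$k_plus, x$k_minus, x$k_e, x$k_r))
  cat(sprintf("  overall K_D = %g M\n", overall_kd(x)))
  invisible(x)
}

#' Overall dissociation constant of a three-state binding scheme
#'
#' The equilibrium dissociation constant of the full scheme, i.e. the
#' free-ligand concentration at which half of the receptor is bound
#' (counting both bound species for induced fit):
#' \deqn{K_D^{IF} = \frac{k_- k_e}{k_+ (k_e + k_r)}, \qquad
#'       K_D^{CS} = \frac{k_- (k_e + k_r)}{k_+ k_e}.}
#'
#' @param params A [mechanism_params()] object.
#' @return Overall dissociation constant (molar).
#' @export
overall_kd <- function(params) {
  stopifnot(inherits(params, "mechanism_params"))
  with(params, {
    if (k_plus <= 0) stop("invalid parameter: k_plus must be > 0 to define K_D")
    if (model == "IF") {
      if (k_e + k_r <= 0) stop("invalid parameter: k_e + k_r must be > 0 (IF)")
      k_minus * k_e / (k_plus * (k_e + k_r))
    } else {
      if (k_e <= 0) stop("invalid parameter: k_e must be > 0 (CS)")
      k_minus * (k_e + k_r) / (k_plus * k_e)
    }
  })
}

#' Association rate constant implied by a fixed overall dissociation constant
#'
#' Inverts the overall-K_D expression of the chosen scheme for `k_plus`.
#' This implements the substitution used in joint rate fitting, where the
#' association rate constant is eliminated in favour of an experimentally
#' determined K_D so that only `k_e`, `k_r` and `k_minus` remain free.
#'
#' @param K_D Overall dissociation constant (molar), > 0.
#' @param k_minus,k_e,k_r Rate constants (/s).
#' @param model `"IF"` or `"CS"`.
#' @return `k_plus` (/M/s) such that [overall_kd()] of the assembled
#'   parameter set returns `K_D`.
#' @export
k_plus_from_kd <- function(K_D, k_minus, k_e, k_r, model = c("IF", "CS")) {
  model <- match.arg(model)
  if (!is.finite(K_D) || K_D <= 0) stop("invalid parameter: K_D must be > 0")
  if (k_e <= 0) stop("invalid parameter: k_e must be > 0 to invert K_D")
  if (model == "IF") {
    if (k_e + k_r <= 0) stop("invalid parameter: k_e + k_r must be > 0")
    k_minus * k_e / (K_D * (k_e + k_r))
  } else {
    k_minus * (k_e + k_r) / (K_D * k_e)
  }
}

#' Two-state binding equilibrium at total concentrations
#'
#' Solves the binding quadratic for a receptor-ligand pair with overall
#' dissociation constant `K_D` at total (after-mixing) ligand and receptor
#' concentrations `L0` and `P0`. The discriminant-like quantity
#' \deqn{\delta = \sqrt{(L_0 - P_0 + K_D)^2 + 4 P_0 K_D}}
#' enters the closed-form relaxation rates; the equilibrium free-ligand and
#' total-bound concentrations follow from it. A numerically stable root is
#' used so that no precision is lost when `P0 >> L0` or `L0 ~ P0 >> K_D`.
#'
#' @param L0 Total ligand concentration (molar), >= 0.
#' @param P0 Total receptor concentration (molar), > 0.
#' @param K_D Overall dissociation constant (molar), >= 0.
#' @return A list of class `binding_equilibrium` with elements `delta`,
#'   `L_free_eq` and `RL_total_eq` (all molar).
#' @export
equilibrium_delta <- function(L0, P0, K_D) {
  if (any(!is.finite(c(L0, P0, K_D))) || L0 < 0 || P0 <= 0 || K_D < 0) {
    stop("require L0 >= 0, P0 > 0, K_D >= 0 and all finite")
  }
  b <- P0 - L0 + K_D            # L_free solves x^2 + b x - K_D L0 = 0
  delta <- sqrt((L0 - P0 + K_D)^2 + 4 * P0 * K_D)
  L_free <- if (b >= 0) {
    if (delta + b > 0) 2 * K_D * L0 / (delta + b) else 0
  } else {
    (delta - b) / 2
  }
  structure(list(delta = delta, L_free_eq = L_free, RL_total_eq = L0 - L_free),
            class = "binding_equilibrium")
}

# Vectorised closed-form relaxation rates; the workhorse behind
# relaxation_rates() and the mechanism chi-square objective. Returns a list
# with k1, k2 and the auxiliary quantities. Cancellation-safe: the smaller
# eigenrate is computed as a quotient when the auxiliary rate is large.
relax_rates_core <- function(model, k_e, k_r, k_minus, k_plus, L0, P0) {
  K_D <- if (model == "IF") {
    k_minus * k_e / (k_plus * (k_e + k_r))
  } else {
    k_minus * (k_e + k_r) / (k_plus * k_e)
  }
  delta <- sqrt((L0 - P0 + K_D)^2 + 4 * P0 * K_D)
  if (model == "IF") {
    gamma <- -k_e - k_r + k_minus + k_plus * (delta - K_D)
    c2 <- 4 * k_minus * k_r
    s <- sqrt(gamma^2 + c2)
    # k1 = ke+kr+(gamma+s)/2, k2 = ke+kr+(gamma-s)/2, stable both signs
    half_sum <- ifelse(gamma >= 0, (gamma + s) / 2, ifelse(s - gamma > 0, c2 / (2 * (s - gamma)), 0))
    half_dif <- ifelse(gamma >= 0, ifelse(gamma + s > 0, -c2 / (2 * (gamma + s)), 0), (gamma - s) / 2)
    k1 <- k_e + k_r + half_sum
    k2 <- k_e + k_r + half_dif
    list(k1 = pmax(k1, k2), k2 = pmin(k1, k2),
         gamma = gamma, delta = delta, K_D = K_D)
  } else {
    alpha <- k_r - k_e +
      k_minus * ((2 * k_e + k_r) * delta + k_r * (L0 - P0 - K_D)) / (2 * k_e * K_D)
    beta <- 2 * k_r * (2 * k_e - k_minus - k_minus * (delta - L0 + P0) / K_D)
    rad <- alpha^2 + beta
    if (any(rad < 0)) {
      err <- structure(
        class = c("relaxkin_domain_error", "error", "condition"),
        list(message = sprintf(
               "negative radicand alpha^2 + beta = %g in CS relaxation rates",
               min(rad)),
             call = sys.call(-1),
             intermediates = list(alpha = alpha, beta = beta, delta = delta,
                                  K_D = K_D)))
      stop(err)
    }
    s <- sqrt(rad)
    half_sum <- ifelse(alpha >= 0, (alpha + s) / 2, ifelse(s - alpha > 0, beta / (2 * (s - alpha)), 0))
    half_dif <- ifelse(alpha >= 0, ifelse(alpha + s > 0, -beta / (2 * (alpha + s)), 0), (alpha - s) / 2)
    k1 <- k_e + half_sum
    k2 <- k_e + half_dif
    list(k1 = pmax(k1, k2), k2 = pmin(k1, k2),
         alpha = alpha, beta = beta, delta = delta, K_D = K_D)
  }
}

#' Closed-form near-equilibrium relaxation rates
#'
#' The two characteristic rates of the final double-exponential relaxation
#' into binding equilibrium, obtained by linearising the mass-action rate
#' equations around the equilibrium concentrations. The result is valid at
#' all total receptor and ligand concentrations and contains the
#' pseudo-first-order result as the large-`L0` limit.
#'
#' For induced fit:
#' \deqn{k_{1,2} = k_e + k_r + \gamma/2 \pm \sqrt{\gamma^2 + 4 k_- k_r}/2,
#'       \quad \gamma = -k_e - k_r + k_- + k_+ (\delta - K_D)}
#' (the radicand term `4 k_- k_r` makes these exactly the eigenvalues of
#' the scheme's linearised rate equations: the trace-determinant identity
#' requires the relaxation rate constant, not the excitation one, alongside
#' `k_-`; see the methods vignette)
#' and for conformational selection:
#' \deqn{k_{1,2} = k_e + \alpha/2 \pm \sqrt{\alpha^2 + \beta}/2}
#' with
#' \deqn{\alpha = k_r - k_e + \frac{k_- ((2 k_e + k_r)\delta +
#'       k_r (L_0 - P_0 - K_D))}{2 k_e K_D}, \quad
#'       \beta = 2 k_r \left(2 k_e - k_- -
#'       \frac{k_- (\delta - L_0 + P_0)}{K_D}\right),}
#' where \eqn{\delta} is the binding-quadratic discriminant of
#' [equilibrium_delta()] and \eqn{K_D} the overall dissociation constant.
#'
#' @param params A [mechanism_params()] object.
#' @param L0,P0 Total ligand and receptor concentrations after mixing (molar).
#' @return A list of class `relaxation_rates` with `k1 >= k2` (/s) and an
#'   `intermediates` list carrying `gamma` (IF) or `alpha`, `beta` (CS) plus
#'   `delta` and the overall `K_D`, so each auxiliary quantity can be
#'   inspected individually.
#' @seealso [eigenrate_oracle()] for the numerical cross-check.
#' @export
relaxation_rates <- function(params, L0, P0) {
  stopifnot(inherits(params, "mechanism_params"))
  if (any(!is.finite(c(L0, P0))) || any(L0 < 0) || P0 <= 0) {
    stop("require L0 >= 0 and P0 > 0")
  }
  r <- relax_rates_core(params$model, params$k_e, params$k_r,
                        params$k_minus, params$k_plus, L0, P0)
  inter <- r[setdiff(names(r), c("k1", "k2"))]
  structure(list(k1 = r$k1, k2 = r$k2, model = params$model,
                 intermediates = inter),
            class = "relaxation_rates")
}

#' Mass-action time derivatives of a three-state binding scheme
#'
#' Right-hand side of the mass-action rate equations for the scheme in
#' `params`. Species are named: `R1, L, R1L, R2L` for induced fit and
#' `R1, R2, L, R2L` for conformational selection. Receptor-sum and
#' ligand-sum derivatives vanish identically.
#'
#' @param state Named numeric vector of species concentrations (molar).
#' @param params A [mechanism_params()] object.
#' @return Named numeric vector of time derivatives (molar/s), same order
#'   as `state`.
#' @export
mass_action_derivatives <- function(state, params) {
  stopifnot(inherits(params, "mechanism_params"))
  need <- if (params$model == "IF") c("R1", "L", "R1L", "R2L")
          else c("R1", "R2", "L", "R2L")
  if (!all(need %in% names(state))) {
    stop("state must contain species ", paste(need, collapse = ", "),
         " for the ", params$model, " scheme")
  }
  with(as.list(c(state, params[c("k_plus", "k_minus", "k_e", "k_r")])), {
    if (params$model == "IF") {
      bind <- k_plus * R1 * L - k_minus * R1L
      conf <- k_r * R1L - k_e * R2L
      c(R1 = -bind, L = -bind, R1L = bind - conf, R2L = conf)[names(state)]
    } else {
      conf <- k_e * R1 - k_r * R2
      bind <- k_plus * R2 * L - k_minus * R2L
      c(R1 = -conf, R2 = conf - bind, L = -bind, R2L = bind)[names(state)]
    }
  })
}

# Full equilibrium species vector for either scheme at totals L0, P0.
# Bound receptor splits R1L:R2L = k_e:k_r at IF equilibrium (k_r[R1L]=k_e[R2L]);
# unbound receptor splits R1:R2 = k_r:k_e at CS equilibrium.
equilibrium_state <- function(params, L0, P0) {
  eq <- equilibrium_delta(L0, P0, overall_kd(params))
  bound <- eq$RL_total_eq
  free_rec <- P0 - bound
  if (params$model == "IF") {
    ker <- params$k_e + params$k_r
    c(R1 = free_rec, L = eq$L_free_eq,
      R1L = bound * params$k_e / ker, R2L = bound * params$k_r / ker)
  } else {
    ker <- params$k_e + params$k_r
    c(R1 = free_rec * params$k_r / ker, R2 = free_rec * params$k_e / ker,
      L = eq$L_free_eq, R2L = bound)
  }
}

#' Relaxation rates by numerical linearisation (brute-force oracle)
#'
#' Computes the relaxation rates of the scheme by linearising
#' [mass_action_derivatives()] at the equilibrium point, independently of
#' the closed-form expressions. The two conservation laws (receptor and
#' ligand totals) are eliminated analytically, leaving a 2x2 Jacobian on the
#' independent coordinates, whose eigenvalues are obtained by central finite
#' differences (exact for mass action up to round-off, since the rate
#' equations are quadratic in the concentrations). Serves as the
#' independent cross-check for [relaxation_rates()].
#'
#' @inheritParams relaxation_rates
#' @return A list with `k1 >= k2`: the negated eigenvalues (/s).
#' @export
eigenrate_oracle <- function(params, L0, P0) {
  stopifnot(inherits(params, "mechanism_params"))
  eqs <- equilibrium_state(params, L0, P0)
  if (params$model == "IF") {
    # coordinates x = [R1L], y = [R2L]; R1 = P0-x-y, L = L0-x-y
    f <- function(x, y) {
      s <- c(R1 = P0 - x - y, L = L0 - x - y, R1L = x, R2L = y)
      mass_action_derivatives(s, params)[c("R1L", "R2L")]
    }
    x0 <- eqs[["R1L"]]; y0 <- eqs[["R2L"]]
  } else {
    # coordinates x = [R2], y = [R2L]; R1 = P0-x-y, L = L0-y
    f <- function(x, y) {
      s <- c(R1 = P0 - x - y, R2 = x, L = L0 - y, R2L = y)
      mass_action_derivatives(s, params)[c("R2", "R2L")]
    }
    x0 <- eqs[["R2"]]; y0 <- eqs[["R2L"]]
  }
  # mass action is quadratic in the concentrations, so the central
  # difference is exact for any step; a generous step minimises round-off
  scale <- max(P0, L0)
  h <- 1e-3 * scale
  J <- cbind((f(x0 + h, y0) - f(x0 - h, y0)) / (2 * h),
             (f(x0, y0 + h) - f(x0, y0 - h)) / (2 * h))
  ev <- eigen(J, only.values = TRUE)$values
  if (is.complex(ev)) {
    if (max(abs(Im(ev))) > 1e-10 * max(abs(ev))) {
      stop("complex eigenvalues at equilibrium; scheme should relax monotonically")
    }
    ev <- Re(ev)
  }
  rates <- sort(-ev, decreasing = TRUE)
  list(k1 = rates[1], k2 = rates[2])
}
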