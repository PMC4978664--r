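#' Model parameters for the delayed diffusive logistic model with feedback control
#'
#' Constructs and validates the parameter set of the model
#' \deqn{\partial_t N = d_1 \Delta N + r N\left[1 - \frac{a_1 N + a_2 N_\tau}{K} - c u\right],\qquad
#'       \partial_t u = d_2 \Delta u + b N_\tau - a u,}
#' posed on the interval \eqn{(0, l\pi)} with no-flux (Neumann) boundaries,
#' where \eqn{N_\tau(x,t) = N(x, t-\tau)} is the delayed population density and
#' \eqn{u} is an indirect control variable produced from the delayed population
#' at rate \eqn{b} and decaying at rate \eqn{a}.
#'
#' All ten constants must be strictly positive. The delay \eqn{\tau} is not a
#' model parameter here; it is passed separately to the analysis and
#' simulation functions, which treat it as the bifurcation parameter.
#'
#' @param d1,d2 Diffusion coefficients of \eqn{N} and \eqn{u}
#'   (length\eqn{^2}/time).
#' @param r Intrinsic growth rate (1/time).
#' @param K Carrying-capacity scale of the logistic term.
#' @param a1 Instantaneous self-limitation weight.
#' @param a2 Delayed self-limitation weight.
#' @param c Coupling of the control variable into the growth term.
#' @param b Production rate of control from the delayed population.
#' @param a Linear decay rate of the control variable.
#' @param l Domain scale: the habitat is the interval \eqn{(0, l\pi)}.
#'
#' @return An object of class `"rdlf_params"`: a named list of the ten
#'   constants.
#'
#' @examples
#' p <- model_params(
#'   d1 = 1, d2 = 0.5, r = 0.6, K = 1,
#'   a1 = 2, a2 = 2, c = 1, b = 1, a = 1, l = 2
#' )
#' equilibria(p)
#' @seealso [example_params()], [read_params()], [equilibria()],
#'   [mode_coefficients()]
#' @export
model_params <- function(d1, d2, r, K, a1, a2, c, b, a, l) {
  p <- list(d1 = d1, d2 = d2, r = r, K = K, a1 = a1, a2 = a2,
            c = c, b = b, a = a, l = l)
  validate_params(p)
}

param_names <- c("d1", "d2", "r", "K", "a1", "a2", "c", "b", "a", "l")

validate_params <- function(p) {
  if (!setequal(names(p), param_names)) {
    extra <- setdiff(names(p), param_names)
    missing <- setdiff(param_names, names(p))
    msg <- "Invalid parameter set."
    if (length(extra)) msg <- paste0(msg, " Unknown fields: ", toString(extra), ".")
    if (length(missing)) msg <- paste0(msg, " Missing fields: ", toString(missing), ".")
    abort(msg, class = "rdlf_params_error")
  }
  p <- p[param_names]
  for (nm in param_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(
        paste0("Parameter '", nm, "' must be a single strictly positive number."),
        class = "rdlf_params_error"
      )
    }
    p[[nm]] <- as.numeric(v)
  }
  structure(p, class = "rdlf_params")
}

#' Reference example parameter set
#'
#' The parameter set used throughout the package documentation, examples and
#' tests: `d1 = 1`, `d2 = 0.5`, `r = 0.6`, `a = b = c = K = 1` (with
#' `a1 = a2 = 2`) on the domain \eqn{(0, 2\pi)}. With these values the
#' positive equilibrium is \eqn{E^* = (0.2, 0.2)}, only the homogeneous
#' spatial mode can lose stability, and the first critical delay of the
#' reduced linearization is \eqn{\tau_0 \approx 5.81966}.
#'
#' @return An `"rdlf_params"` object.
#' @examples
#' classify_stability(example_params(), tau = 2)
#' @export
example_params <- function() {
  model_params(d1 = 1, d2 = 0.5, r = 0.6, K = 1,
               a1 = 2, a2 = 2, c = 1, b = 1, a = 1, l = 2)
}

#' Read a parameter file
#'
#' Reads the ten model constants from a flat YAML or JSON file. Unknown keys
#' are rejected, as are missing or non-positive values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose top level is a
#'   flat mapping with exactly the fields documented in [model_params()].
#' @return An `"rdlf_params"` object.
#' @examples
#' f <- system.file("extdata", "example_params.yaml", package = "rdlogistic")
#' read_params(f)
#' @export
read_params <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Parameter file not found: ", path), class = "rdlf_params_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_params(as.list(raw))
}

#' @export
print.rdlf_params <- function(x, ...) {
  cat("Delayed diffusive logistic model parameters (domain (0, ",
      format(x$l), "π))\n", sep = "")
  vals <- unlist(x)
  print(vals)
  invisible(x)
}

#' @export
as_tibble.rdlf_params <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
as.list.rdlf_params <- function(x, ...) unclass(x)
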