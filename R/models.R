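#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn `%||%`
#' @importFrom stats lm coef qt var sd median quantile dnorm dlnorm dunif
#'   runif rnorm rlnorm optimize optim complete.cases setNames density bw.nrd
#' @import tibble
NULL

## Model registry -----------------------------------------------------------

.timerr_models <- list(
  linear   = c("beta0", "beta_x"),
  cosine   = c("a", "b"),
  parasite = c("V0", "g", "B0", "k"),
  gompertz = c("y0", "r", "K"),
  glut4    = c("P0", "k", "M")
)

#' Names of the deterministic models
#'
#' The package ships five closed-form models used throughout the synthetic
#' studies: a straight line, a cosine oscillator, a two-exponential parasite
#' growth curve with decaying background fluorescence, Gompertz tumour
#' growth, and a two-compartment GLUT4 translocation model (exponential rise
#' to a plateau).
#'
#' @return Character vector of model identifiers.
#' @export
model_ids <- function() names(.timerr_models)

#' Parameter names for a model
#'
#' @param model_id One of `model_ids()`.
#' @return Character vector of parameter names, in canonical order.
#' @export
model_par_names <- function(model_id) {
  model_id <- match.arg(model_id, model_ids())
  .timerr_models[[model_id]]
}

new_params <- function(model_id, values, extra = list()) {
  structure(
    c(as.list(values), extra),
    class = c(paste0(model_id, "_params"), "timerr_params"),
    model_id = model_id
  )
}

#' @export
print.timerr_params <- function(x, ...) {
  cat("<", attr(x, "model_id"), " parameters>\n", sep = "")
  vals <- unlist(x[model_par_names(attr(x, "model_id"))])
  print(vals)
  invisible(x)
}

#' Model parameter constructors
#'
#' Validated parameter sets for the five deterministic models. Each
#' constructor checks the domain constraints of its model and returns a
#' classed list accepted by [evaluate_model()] and the fitting functions.
#'
#' * `linear_params()`: intercept `beta0` and slope `beta_x` of
#'   `y = beta0 + beta_x * x`.
#' * `cosine_params()`: amplitude `a >= 0` (response units) and angular
#'   frequency `b` (radians per unit x) of `y = a * cos(b * x)`.
#' * `parasite_params()`: initial parasite level `V0`, growth rate `g`
#'   (per day), initial background fluorescence `B0` and background decay
#'   rate `k` (per day), all non-negative, for
#'   `P(t) = V0 * exp(g * t) + B0 * exp(-k * t)`.
#' * `gompertz_params()`: initial volume `y0` (mm^3), growth rate `r`
#'   (per day) and carrying capacity `K` (mm^3) with `0 < y0 < K`, for
#'   `y(t) = K * (y0 / K)^exp(-r * t)`.
#' * `glut4_params()`: initial plasma-membrane level `P0 >= 0`, effective
#'   rate `k = k_ex + k_en > 0` (per minute) and plateau `M >= 0` of
#'   `P(t) = (P0 - M) * exp(-k * t) + M`. `M` is stored as a free plateau
#'   parameter; the underlying endocytosis/exocytosis rates `k_en`, `k_ex`
#'   may be supplied instead of `k` and `M`, in which case
#'   `k = k_en + k_ex` and `M = k_ex / (k_en + k_ex)`.
#'
#' @param beta0,beta_x Intercept and slope of the linear model.
#' @param a,b Amplitude and angular frequency of the cosine model.
#' @param V0,g,B0 Parasite model parameters (see above).
#' @param y0,r,K Gompertz model parameters (see above).
#' @param P0,k,M GLUT4 model parameters (see above).
#' @param k_en,k_ex Optional endocytosis/exocytosis rates (per minute).
#' @return A `timerr_params` object.
#' @examples
#' evaluate_model(parasite_params(0.002, 0.531, 0.02, 0.323), 0)
#' @name model_params
NULL

check_finite <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", what, "` must be a single finite number"))
  }
  as.numeric(x)
}

#' @rdname model_params
#' @export
linear_params <- function(beta0, beta_x) {
  new_params("linear", c(
    beta0 = check_finite(beta0, "beta0"),
    beta_x = check_finite(beta_x, "beta_x")
  ))
}

#' @rdname model_params
#' @export
cosine_params <- function(a, b) {
  a <- check_finite(a, "a")
  if (a < 0) abort("amplitude `a` must be non-negative")
  new_params("cosine", c(a = a, b = check_finite(b, "b")))
}

#' @rdname model_params
#' @export
parasite_params <- function(V0, g, B0, k) {
  vals <- c(
    V0 = check_finite(V0, "V0"), g = check_finite(g, "g"),
    B0 = check_finite(B0, "B0"), k = check_finite(k, "k")
  )
  if (any(vals < 0)) abort("parasite parameters must all be non-negative")
  new_params("parasite", vals)
}

#' @rdname model_params
#' @export
gompertz_params <- function(y0, r, K) {
  y0 <- check_finite(y0, "y0"); r <- check_finite(r, "r")
  K <- check_finite(K, "K")
  if (y0 <= 0 || K <= y0) abort("Gompertz parameters require 0 < y0 < K")
  if (r <= 0) abort("growth rate `r` must be positive")
  new_params("gompertz", c(y0 = y0, r = r, K = K))
}

#' @rdname model_params
#' @export
glut4_params <- function(P0, k = NULL, M = NULL, k_en = NULL, k_ex = NULL) {
  P0 <- check_finite(P0, "P0")
  if (P0 < 0) abort("`P0` must be non-negative")
  extra <- list()
  if (!is.null(k_en) || !is.null(k_ex)) {
    if (is.null(k_en) || is.null(k_ex)) {
      abort("supply both `k_en` and `k_ex` or neither")
    }
    k_en <- check_finite(k_en, "k_en"); k_ex <- check_finite(k_ex, "k_ex")
    if (k_en < 0 || k_ex < 0) abort("`k_en` and `k_ex` must be non-negative")
    k <- k %||% (k_en + k_ex)
    M <- M %||% (k_ex / (k_en + k_ex))
    extra <- list(k_en = k_en, k_ex = k_ex)
  }
  if (is.null(k) || is.null(M)) abort("supply `k` and `M`, or `k_en`/`k_ex`")
  k <- check_finite(k, "k"); M <- check_finite(M, "M")
  if (k <= 0) abort("effective rate `k` must be positive")
  if (M < 0) abort("plateau `M` must be non-negative")
  new_params("glut4", c(P0 = P0, k = k, M = M), extra = extra)
}

as_param_vector <- function(model_id, params) {
  nms <- model_par_names(model_id)
  if (inherits(params, "timerr_params")) {
    if (!identical(attr(params, "model_id"), model_id)) {
      abort(paste0("parameters are for model '", attr(params, "model_id"),
                   "', not '", model_id, "'"))
    }
  }
  vals <- unlist(params[nms])
  if (length(vals) != length(nms) || any(!is.finite(vals))) {
    abort(paste0("parameters for '", model_id, "' must supply finite values ",
                 "named ", paste(nms, collapse = ", ")))
  }
  vals
}

## Model evaluation ---------------------------------------------------------

#' Evaluate a deterministic model
#'
#' Pure, vectorised evaluation of one of the five closed-form models at the
#' independent-variable values `x` (time, in the units of the model). No
#' randomness is involved.
#'
#' @param params A `timerr_params` object (or a named list/vector with the
#'   parameters of `model_id`; then `model_id` must be given explicitly).
#' @param x Numeric vector of independent-variable values.
#' @param model_id Model identifier; defaults to the one recorded in
#'   `params`.
#' @return Numeric vector of model responses, same length as `x`.
#' @examples
#' evaluate_model(gompertz_params(110, 0.08, 4000), 60)
#' @export
evaluate_model <- function(params, x, model_id = NULL) {
  model_id <- model_id %||% attr(params, "model_id")
  if (is.null(model_id)) abort("`model_id` must be given for plain parameter lists")
  model_id <- match.arg(model_id, model_ids())
  if (!is.numeric(x) || any(!is.finite(x))) abort("`x` must be finite numeric")
  p <- as_param_vector(model_id, params)
  switch(model_id,
    linear   = p[["beta0"]] + p[["beta_x"]] * x,
    cosine   = p[["a"]] * cos(p[["b"]] * x),
    parasite = p[["V0"]] * exp(p[["g"]] * x) + p[["B0"]] * exp(-p[["k"]] * x),
    gompertz = p[["K"]] * (p[["y0"]] / p[["K"]])^exp(-p[["r"]] * x),
    glut4    = (p[["P0"]] - p[["M"]]) * exp(-p[["k"]] * x) + p[["M"]]
  )
}

## Lognormal re-parameterisation --------------------------------------------

#' Lognormal parameters from original-scale moments
#'
#' Converts a target mean and variance on the original scale into the
#' log-scale location `mu` and squared scale `sigma2` of the lognormal
#' distribution with those moments:
#' `mu = log(m^2 / sqrt(m^2 + v))`, `sigma2 = log(1 + v / m^2)`.
#'
#' A zero target variance yields the degenerate point mass (`sigma2 = 0`),
#' flagged via the `degenerate` field.
#'
#' @param target_mean Mean on the original scale (> 0).
#' @param target_var Variance on the original scale (>= 0).
#' @return A list with `mu`, `sigma2`, `target_mean`, `target_var`,
#'   `degenerate`.
#' @examples
#' lognormal_from_moments(1 / 6, 0.01)
#' @export
lognormal_from_moments <- function(target_mean, target_var) {
  target_mean <- check_finite(target_mean, "target_mean")
  target_var <- check_finite(target_var, "target_var")
  if (target_mean <= 0) abort("`target_mean` must be positive")
  if (target_var < 0) abort("`target_var` must be non-negative")
  m2 <- target_mean^2
  list(
    mu = log(m2 / sqrt(m2 + target_var)),
    sigma2 = log1p(target_var / m2),
    target_mean = target_mean,
    target_var = target_var,
    degenerate = target_var == 0
  )
}

## Config serialisation -----------------------------------------------------

#' Serialise / deserialise model parameters
#'
#' `params_config()` flattens a parameter object into a plain named list
#' (with a `model_id` tag) suitable for YAML/JSON serialisation;
#' `params_from_config()` reverses it.
#'
#' @param params A `timerr_params` object.
#' @param config A list as produced by `params_config()`.
#' @return A plain list, or a `timerr_params` object.
#' @export
params_config <- function(params) {
  stopifnot(inherits(params, "timerr_params"))
  c(list(model_id = attr(params, "model_id")),
    lapply(params, identity))
}

#' @rdname params_config
#' @export
params_from_config <- function(config) {
  model_id <- match.arg(config$model_id, model_ids())
  args <- config[setdiff(names(config), "model_id")]
  ctor <- switch(model_id,
    linear = linear_params, cosine = cosine_params,
    parasite = parasite_params, gompertz = gompertz_params,
    glut4 = glut4_params
  )
  do.call(ctor, args)
}
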