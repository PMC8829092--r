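#' @include msd.R
NULL

# localisation-error contribution to D_app; delta is the localisation error
# in metres (the fitted parameter), R the blur coefficient and dt the frame
# interval of the track being analysed
.deltaTerm <- function(t, delta, R, dt) {
  delta^2 / (2 * t * (1 - 2 * R * dt / t))
}

#' Construct a diffusion model for ADC fitting
#'
#' The curve function receives the lag times, a named parameter vector, the
#' blur coefficient R and the track time step dt, and must return D_app
#' values (m^2/s), i.e. the model diffusion law plus any localisation-error
#' term the model wishes to carry.
#'
#' @param name unique model name.
#' @param paramNames character vector of free-parameter names.
#' @param fun function(t, params, R, dt) -> D_app values.
#' @param lower,upper,initial numeric vectors aligned with paramNames;
#'   must satisfy lower <= initial <= upper.
#' @return a validated \linkS4class{DiffusionModel}.
#' @export
DiffusionModel <- function(name, paramNames, fun, lower, upper, initial) {
  new("DiffusionModel", name = name, paramNames = paramNames,
      lower = as.numeric(lower), upper = as.numeric(upper),
      initial = as.numeric(initial), fun = fun)
}

#' Built-in diffusion models
#'
#' Returns a registry with the three standard models, each including the
#' localisation-error term delta^2 / (2 t (1 - 2 R dt / t)):
#' \describe{
#'   \item{brownian}{free diffusion, D(t) = D}
#'   \item{confined}{confined diffusion, D(t) = D (tau/t) (1 - exp(-t/tau));
#'     tends to D at short times and decays to zero transport at long times.
#'     D here is the microscopic coefficient D_mu inside the confinement
#'     zone of size L = sqrt(12 D_mu tau).}
#'   \item{hop}{compartmentalised (hop) diffusion, the sum of the two:
#'     D(t) = Dm + Dmu (tau/t) (1 - exp(-t/tau)), with Dm the long-time
#'     macroscopic coefficient.}
#' }
#' delta (metres, >= 0) is the fitted localisation-error parameter.
#'
#' @return a \linkS4class{ModelRegistry}.
#' @examples
#' reg <- builtinModels()
#' modelNames(reg)
#' @export
builtinModels <- function() {
  brownian <- DiffusionModel(
    "brownian", c("D", "delta"),
    function(t, p, R, dt) p[["D"]] + .deltaTerm(t, p[["delta"]], R, dt),
    lower = c(0, 0), upper = c(Inf, Inf), initial = c(0.5e-12, 2e-9))
  confined <- DiffusionModel(
    "confined", c("D", "delta", "tau"),
    function(t, p, R, dt)
      p[["D"]] * (p[["tau"]] / t) * (1 - exp(-t / p[["tau"]])) +
        .deltaTerm(t, p[["delta"]], R, dt),
    lower = c(0, 0, 1e-12), upper = c(Inf, Inf, Inf),
    initial = c(0.5e-12, 2e-9, 1e-2))
  hop <- DiffusionModel(
    "hop", c("Dm", "Dmu", "delta", "tau"),
    function(t, p, R, dt)
      p[["Dm"]] + p[["Dmu"]] * (p[["tau"]] / t) * (1 - exp(-t / p[["tau"]])) +
        .deltaTerm(t, p[["delta"]], R, dt),
    lower = c(0, 0, 0, 1e-12), upper = c(Inf, Inf, Inf, Inf),
    initial = c(0.5e-12, 0.5e-12, 2e-9, 1e-2))
  new("ModelRegistry",
      models = list(brownian = brownian, confined = confined, hop = hop))
}

#' An empty model registry
#'
#' Starting point for analyses that should use only custom models.
#' @return a \linkS4class{ModelRegistry} with no models.
#' @export
emptyRegistry <- function() new("ModelRegistry", models = list())

#' Register a diffusion model
#'
#' Adds a model to a registry; subsequent analyses fit it alongside (or, for
#' a fresh registry, instead of) the built-ins. Fit order is registration
#' order, which also breaks BIC ties.
#'
#' @param registry a \linkS4class{ModelRegistry}.
#' @param model a \linkS4class{DiffusionModel}.
#' @return the extended registry.
#' @export
registerModel <- function(registry, model) {
  stopifnot(is(registry, "ModelRegistry"), is(model, "DiffusionModel"))
  if (model@name %in% names(registry@models))
    stop("registry error: a model named '", model@name,
         "' is already registered")
  registry@models[[model@name]] <- model
  validObject(registry)
  registry
}

setMethod("modelNames", "ModelRegistry",
  function(x) unname(vapply(x@models, function(m) m@name, character(1))))

#' ModelRegistry accessors
#' @param x a \linkS4class{ModelRegistry}.
#' @name ModelRegistry-accessors
NULL

setMethod("show", "DiffusionModel", function(object) {
  cat(sprintf("DiffusionModel '%s' (%s)\n", object@name,
              paste(object@paramNames, collapse = ", ")))
})

setMethod("show", "ModelRegistry", function(object) {
  cat(sprintf("ModelRegistry with %d model(s): %s\n", length(object@models),
              paste(modelNames(object), collapse = ", ")))
})
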