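#' Default sub-model coefficient sets
#'
#' The daily mass balance is assembled from parametric sub-models (energy
#' requirement, drinking-water intake on pasture and in the stall, lung
#' ventilation, transcutaneous vapor, product and urea export, silage-water
#' and cellulose delta-18O, stoichiometric constants). Their default
#' coefficients ship as a YAML file inside the package; every set carries a
#' `provenance` string saying where its parametric form comes from.
#'
#' @param overrides optional named nested list; values replace the packaged
#'   defaults. Unknown set or coefficient names are an error, so typos are
#'   caught rather than silently ignored.
#' @return A nested named list of coefficient sets, class `isocow_coefficients`.
#' @examples
#' co <- default_coefficients()
#' names(co)
#' co$stoichiometry$mol_o_per_kg_water
#' default_coefficients(list(transcutaneous = list(e0_w_per_m2 = 0)))
#' @export
default_coefficients <- function(overrides = NULL) {
  co <- .coefficients_cache()
  if (!is.null(overrides)) {
    co <- modify_named(co, overrides, what = "coefficient")
  }
  class(co) <- c("isocow_coefficients", "list")
  co
}

.coef_env <- new.env(parent = emptyenv())

.coefficients_cache <- function() {
  if (is.null(.coef_env$co)) {
    path <- system.file("extdata", "coefficients.yaml", package = "isocow")
    if (!nzchar(path)) {
      stop("packaged coefficient file not found; is the package installed?")
    }
    co <- yaml::read_yaml(path)
    for (set in names(co)) {
      if (is.null(co[[set]]$provenance)) {
        stop("coefficient set '", set, "' lacks a provenance string")
      }
    }
    .coef_env$co <- co
  }
  .coef_env$co
}

# Recursively merge `new` into `base`, refusing keys absent from `base`.
# Shared by coefficient overrides and run-config loading.
modify_named <- function(base, new, what = "key", path = character()) {
  if (!is.list(new)) {
    return(new)
  }
  if (length(new) == 0) {
    return(base)
  }
  nm <- names(new)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("all ", what, " overrides must be named")
  }
  for (k in nm) {
    full <- paste(c(path, k), collapse = "$")
    if (!k %in% names(base)) {
      stop("unknown ", what, " '", full, "'")
    }
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- modify_named(base[[k]], new[[k]], what, c(path, k))
    } else {
      base[[k]] <- new[[k]]
    }
  }
  base
}
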