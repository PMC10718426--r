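#' Competition parameters
#'
#' Bundles the parameters shared by every model in the package: the channel
#' size (total population) `N`, the relative fitness `w` of species 1, and
#' the basal division rate `r`.
#'
#' The relative fitness is related to the selection coefficient of classical
#' population genetics by `w = 1 + s`; either may be supplied.  With the
#' default \code{r = 1} one unit of time corresponds to approximately one
#' generation in both models: the total division rate of the spatial channel
#' is \code{r * (N - 1)} (close to `N` divisions per unit time) and the Moran
#' process is scheduled at `N` birth-death events per unit time.
#'
#' @param N Integer total population / channel length in cells.  The spatial
#'   exclusion model requires `N >= 3`: at `N = 2` both boundary-motion rates
#'   vanish at the interior state and the `(N - 1)` direction-bias
#'   normalisation degenerates.  The Moran model accepts `N >= 2`.
#' @param w Relative fitness of species 1 (strictly positive).  Exactly one
#'   of `w` and `s` may be given; the other is derived.
#' @param s Selection coefficient, `s = w - 1`.
#' @param r Basal division rate (strictly positive, default 1).
#'
#' @return An object of class `competition_params`: a list with elements
#'   `N`, `w`, `s` and `r`.
#'
#' @examples
#' competition_params(N = 100, w = 1.5)
#' competition_params(N = 100, s = 0.5)  # identical
#'
#' @seealso [spatial_rates()], [moran_rates()]
#' @export
competition_params <- function(N, w = NULL, s = NULL, r = 1) {
  if (!is.null(w) && !is.null(s) && abs(w - (1 + s)) > 1e-12)
    stop("supply either 'w' or 's' (they must satisfy w = 1 + s)")
  if (is.null(w)) w <- if (is.null(s)) 1 else 1 + s
  if (length(N) != 1L || !is.finite(N) || N != round(N) || N < 2)
    stop("'N' must be a single integer >= 2")
  if (length(w) != 1L || !is.finite(w) || w <= 0)
    stop("'w' must be a single positive number")
  if (length(r) != 1L || !is.finite(r) || r <= 0)
    stop("'r' must be a single positive number")
  structure(list(N = as.integer(N), w = as.numeric(w),
                 s = as.numeric(w) - 1, r = as.numeric(r)),
            class = "competition_params")
}

#' @export
print.competition_params <- function(x, ...) {
  cat("Competition parameters\n")
  cat(sprintf("  N (channel size)     : %d\n", x$N))
  cat(sprintf("  w (relative fitness) : %g  (s = %g)\n", x$w, x$s))
  cat(sprintf("  r (basal rate)       : %g\n", x$r))
  invisible(x)
}

as_competition_params <- function(x) {
  if (inherits(x, "competition_params")) return(x)
  stop("expected a 'competition_params' object; see competition_params()")
}

#' Read or write parameters as a flat key-value config file
#'
#' The config format is a flat YAML mapping with keys `N`, `w` (or `s`),
#' `r` and optionally `model` (`"spatial"` or `"moran"`).
#'
#' @param path Path of the config file.
#' @return `read_params_config()` returns a list with elements `params`
#'   (a [competition_params()] object) and `model` (character or `NULL`).
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare key "N" as the boolean FALSE; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "N"
  if (is.null(cfg$N)) stop("config file must define 'N'")
  p <- competition_params(N = cfg$N, w = cfg$w, s = cfg$s,
                          r = if (is.null(cfg$r)) 1 else cfg$r)
  model <- cfg$model
  if (!is.null(model)) model <- match.arg(model, c("spatial", "moran"))
  list(params = p, model = model)
}

#' @rdname read_params_config
#' @param params A [competition_params()] object.
#' @param model Optional model name stored alongside the parameters.
#' @export
write_params_config <- function(params, path, model = NULL) {
  params <- as_competition_params(params)
  cfg <- list(N = params$N, w = params$w, r = params$r)
  if (!is.null(model)) cfg$model <- match.arg(model, c("spatial", "moran"))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
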