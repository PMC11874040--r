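# Structured-text run configuration: a JSON document with fixed sections;
# unknown keys are rejected so typos fail loudly.  Physical quantities
# carry their unit in the field name (Nm, Rad, counts).

.config_schema <- list(
  optics = c("naA", "naB", "n", "lambdaExNm", "lambdaEmNm", "sigmaLsNm",
             "sigmaDetANm", "sigmaDetBNm"),
  scheme = c("name", "tilt0Rad", "illumView", "psiRad", "tauRad"),
  phantom = c("kind", "dims", "spacingNm", "radiusNm", "widthNm", "kappa",
              "mode", "arrangement", "disorderedFraction",
              "spacingWiresNm", "regionNm", "seed"),
  noise = c("model", "countsPerShellVoxel", "countsPerUnit", "seed"),
  recon = c("eta", "mode", "padVoxels"),
  analysis = c("countThreshold", "maxWireDistNm", "coneDeg")
)

#' Default run configuration
#'
#' The stated world of the demo pipeline: a ~6 um spherical-shell phantom
#' with membrane-normal Watson ODFs (kappa = 5) on 130 nm voxels, the
#' tilted six-measurement scheme, Poisson noise at 5,000 expected total
#' counts per shell voxel, Tikhonov reconstruction at the default eta, and
#' the count > 5,000 / 42-degree-cone analysis thresholds.
#'
#' @return nested list of class "RunConfig".
#' @export
defaultRunConfig <- function() {
  structure(list(
    optics = list(naA = 1.1, naB = 0.67, n = 1.33, lambdaExNm = 488,
                  lambdaEmNm = 500, sigmaLsNm = 500),
    scheme = list(name = "six_with_tilt", tilt0Rad = 20 * pi / 180),
    phantom = list(kind = "guv", dims = c(48L, 48L, 48L), spacingNm = 130,
                   radiusNm = 2600, widthNm = 260, kappa = 5,
                   mode = "normal", seed = 1L),
    noise = list(model = "poisson", countsPerShellVoxel = 5000, seed = 1L),
    recon = list(eta = 0.0032, mode = "factored", padVoxels = 16L),
    analysis = list(countThreshold = 5000, maxWireDistNm = 5000,
                    coneDeg = 42)
  ), class = "RunConfig")
}

#' Read and validate a run configuration
#'
#' @param path JSON config path.
#' @return validated "RunConfig" list merged over the defaults.
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- unclass(defaultRunConfig())
  bad <- setdiff(names(cfg), names(.config_schema))
  if (length(bad)) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         " in ", path)
  }
  for (sec in names(cfg)) {
    unknown <- setdiff(names(cfg[[sec]]), .config_schema[[sec]])
    if (length(unknown)) {
      stop("unknown key(s) in config section '", sec, "': ",
           paste(unknown, collapse = ", "), " in ", path)
    }
    base[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  }
  structure(base, class = "RunConfig")
}

#' @rdname readRunConfig
#' @param cfg a RunConfig; @param path output path.
#' @export
writeRunConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# helpers shared by the CLI and tests
.optics_from_config <- function(rc) {
  o <- rc$optics
  do.call(opticsConfig, o[!vapply(o, is.null, logical(1))])
}

.scheme_from_config <- function(rc) {
  s <- rc$scheme
  if (identical(s$name, "custom")) {
    makeScheme("custom", specs = data.frame(illumView = s$illumView,
                                            psi = s$psiRad, tau = s$tauRad))
  } else {
    tilt0 <- if (is.null(s$tilt0Rad)) 20 * pi / 180 else s$tilt0Rad
    makeScheme(s$name, tilt0 = tilt0)
  }
}
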