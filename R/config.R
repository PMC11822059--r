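## Run configuration: every tunable of the designer/quantifier with its
## documented default, loadable/overridable from YAML.

#' Default run configuration
#'
#' Returns the full default configuration as a named list:
#' \describe{
#'   \item{scaffold}{standard SpCas9 sgRNA scaffold (DNA alphabet).}
#'   \item{dcnWindow}{soft DCN window, default `c(32, 40)` (empirical
#'     optimum at endogenous loci); `"relaxed"` preset `c(25, 71)`,
#'     `"permissive"` preset `c(25, 96)` (reporter-derived range).}
#'   \item{dcnHardMin}{hard DCN floor 25 (24 nt or shorter is avoided).}
#'   \item{pbsLen}{12 (recommended; 9-16 supported).}
#'   \item{hsLen}{16 (recommended starting point; 12-22 tested).}
#'   \item{mismatchScheme, mismatchK, mismatchSide}{flap-mismatch engine
#'     defaults: consecutive, k = 11, auto side.}
#'   \item{helperPolicy}{`"auto"` (attach a Helper gRNA when the ES reaches
#'     `helperEsThreshold` nt and a candidate exists), `"on"`, `"off"`.}
#'   \item{helperEsThreshold}{70 nt.}
#'   \item{helperMinSeparation}{25 nt from either flanking nick.}
#'   \item{quantW}{quantification window flank, 10 nt.}
#'   \item{u6G}{prepend a G to G-less spacers for U6 expression (FALSE).}
#'   \item{maxDesigns}{cap on emitted designs (10).}
#'   \item{seed}{RNG seed for everything stochastic, 1729.}
#' }
#' @return Named list.
#' @export
defaultConfig <- function() {
  list(scaffold = SGRNA_SCAFFOLD,
       dcnWindow = c(32L, 40L),
       dcnHardMin = 25L,
       pbsLen = 12L,
       hsLen = 16L,
       mismatchScheme = "consecutive",
       mismatchK = 11L,
       mismatchSide = "auto",
       helperPolicy = "auto",
       helperEsThreshold = 70L,
       helperMinSeparation = 25L,
       quantW = 10L,
       u6G = FALSE,
       maxDesigns = 10L,
       seed = 1729L)
}

#' Load a configuration, merging user YAML over the defaults
#'
#' @param path Optional YAML file; fields present override the defaults,
#'   everything else keeps its default.
#' @param preset Optional DCN window preset: `"relaxed"` (`[25, 71]`) or
#'   `"permissive"` (`[25, 96]`).
#' @return Named list as [defaultConfig()].
#' @export
loadConfig <- function(path = NULL, preset = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      warning("ignoring unknown config fields: ",
              paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, user[intersect(names(user), names(cfg))])
    cfg$dcnWindow <- as.integer(cfg$dcnWindow)
  }
  if (!is.null(preset)) {
    cfg$dcnWindow <- switch(match.arg(preset, c("relaxed", "permissive")),
                            relaxed = c(25L, 71L),
                            permissive = c(25L, 96L))
  }
  cfg
}

#' Write a configuration as YAML
#' @param cfg Configuration list.
#' @param path Output path (or `stdout()` connection).
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
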