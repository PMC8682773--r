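## cli support: validated run configuration with optional YAML loading.

#' Validated run configuration
#'
#' Collects every tunable of the pipeline with its default: similarity
#' threshold 0.8 and relative pseudocount 0.5 for the DCA layer, filter
#' size 3 in single mode, contact cutoff 10 A, sequence-separation band 4,
#' 5-fold cross-validation repeated 10 times.
#'
#' @param similarityThreshold Sequence-identity fraction in (0, 1].
#' @param lambdaRatio Pseudocount as a fraction of M_eff (lambda =
#'   lambdaRatio * M_eff).
#' @param filterMode `"single"` or `"dual"`.
#' @param filterSize Odd filter size, one of 3, 5, 7.
#' @param topN Pairs reported by prediction (`NULL` = 2 L).
#' @param minSeparation Excluded sequence-separation band.
#' @param contactCutoff Heavy-atom contact cutoff in Angstrom.
#' @param cvK Cross-validation folds.
#' @param cvRepeats Cross-validation repeats.
#' @param seed RNG seed.
#' @return Named list of class `coconetConfig`.
#' @export
coconetConfig <- function(similarityThreshold = 0.8, lambdaRatio = 0.5,
                          filterMode = "single", filterSize = 3L,
                          topN = NULL, minSeparation = 4L,
                          contactCutoff = 10, cvK = 5L, cvRepeats = 10L,
                          seed = 1L) {
  if (similarityThreshold <= 0 || similarityThreshold > 1) {
    stopInput("similarityThreshold must be in (0, 1]")
  }
  if (lambdaRatio < 0) stopInput("lambdaRatio must be >= 0")
  if (!filterMode %in% c("single", "dual")) {
    stopInput("filterMode must be 'single' or 'dual'")
  }
  if (!filterSize %in% c(3L, 5L, 7L)) {
    stopInput("filterSize must be 3, 5 or 7")
  }
  if (contactCutoff <= 0) stopInput("contactCutoff must be positive")
  if (cvK < 2L) stopInput("cvK must be >= 2")
  structure(list(similarityThreshold = similarityThreshold,
                 lambdaRatio = lambdaRatio, filterMode = filterMode,
                 filterSize = as.integer(filterSize), topN = topN,
                 minSeparation = as.integer(minSeparation),
                 contactCutoff = contactCutoff, cvK = as.integer(cvK),
                 cvRepeats = as.integer(cvRepeats),
                 seed = as.integer(seed)),
            class = "coconetConfig")
}

#' Load a configuration from YAML with overrides
#'
#' Reads a YAML file of configuration keys (all optional) and applies any
#' further overrides on top; everything is validated by [coconetConfig()].
#'
#' @param path Optional YAML file path.
#' @param ... Named overrides taking precedence over the file.
#' @return A validated `coconetConfig` list.
#' @export
loadConfig <- function(path = NULL, ...) {
  base <- list()
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopInput("the 'yaml' package is required to read config files")
    }
    base <- yaml::read_yaml(path)
  }
  overrides <- list(...)
  base[names(overrides)] <- overrides
  do.call(coconetConfig, base)
}
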