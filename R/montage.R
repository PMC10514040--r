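#' Montage specification
#'
#' A montage is an ordered set of unique channel labels plus named channel
#' subsets ("region sets") used to place and recover group effects (bilateral
#' temporal/frontotemporal, occipital/parieto-occipital, prefrontal).
#'
#' @param labels character vector of unique channel names.
#' @param region_sets named list of character vectors, each a subset of
#'   `labels`.
#' @return an object of class `montage_spec`.
#' @export
montage_spec <- function(labels, region_sets = list()) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("montage labels must be unique")
  if (length(region_sets)) {
    if (is.null(names(region_sets)) || any(names(region_sets) == ""))
      stop("region_sets must be a named list")
    for (nm in names(region_sets)) {
      bad <- setdiff(region_sets[[nm]], labels)
      if (length(bad))
        stop("region set '", nm, "' contains channels not in the montage: ",
             paste(bad, collapse = ", "))
    }
  }
  structure(list(labels = labels, region_sets = region_sets),
            class = "montage_spec")
}

#' @export
print.montage_spec <- function(x, ...) {
  cat("<montage_spec> ", length(x$labels), " channels\n", sep = "")
  for (nm in names(x$region_sets))
    cat("  ", nm, ": ", paste(x$region_sets[[nm]], collapse = " "), "\n",
        sep = "")
  invisible(x)
}

#' 64-channel BioSemi 10-10 montage
#'
#' The standard BioSemi Active-Two 64-channel cap in 10-10 nomenclature,
#' with region sets for the bilateral temporal/frontotemporal, the
#' occipital/parieto-occipital, and the prefrontal channel groups.
#'
#' @return a [montage_spec].
#' @export
biosemi64_montage <- function() {
  labels <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2")
  montage_spec(labels, list(
    temporal_frontotemporal_left  = c("F7", "FT7", "FC5", "T7", "C5", "TP7"),
    temporal_frontotemporal_right = c("F8", "FT8", "FC6", "T8", "C6", "TP8"),
    occipital_parieto_occipital   = c("PO7", "PO3", "POz", "PO4", "PO8",
                                      "O1", "Oz", "O2", "Iz"),
    prefrontal = c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8")))
}

#' Reduced 16-channel demonstration montage
#'
#' A subset of the 64-channel BioSemi cap that still covers all region sets;
#' intended for fast desk-scale simulations, examples, and tests.
#'
#' @return a [montage_spec].
#' @export
demo_montage <- function() {
  montage_spec(
    c("FT7", "FC5", "T7", "C5", "FT8", "FC6", "T8", "C6",
      "PO3", "POz", "PO4", "Oz", "Fp1", "Fz", "Cz", "Pz"),
    list(
      temporal_frontotemporal_left  = c("FT7", "FC5", "T7", "C5"),
      temporal_frontotemporal_right = c("FT8", "FC6", "T8", "C6"),
      occipital_parieto_occipital   = c("PO3", "POz", "PO4", "Oz"),
      prefrontal = "Fp1"))
}
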