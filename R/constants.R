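# Canonical channel order: all profile concatenations and file columns use it.
.MUSCLES <- c("RF", "VL", "VM", "ST", "BF", "TA", "Sol", "MG", "LG", "FHL", "EDL")

# Environment codes in label order 1..5.
.ENVIRONMENTS <- c("FGW", "US", "DS", "UW", "DW")

.ENVIRONMENT_NAMES <- c(
  FGW = "flat-ground", US = "upstairs", DS = "downstairs",
  UW = "uphill", DW = "downhill"
)

#' Canonical muscle set
#'
#' The eleven lower-limb muscles the pipeline recognises, in the fixed
#' order used for every profile concatenation and file layout: rectus
#' femoris (RF), vastus lateralis (VL), vastus medialis (VM),
#' semitendinosus (ST), biceps femoris (BF), tibialis anterior (TA),
#' soleus (Sol), medial/lateral gastrocnemius (MG, LG), flexor hallucis
#' longus (FHL) and extensor digitorum longus (EDL).
#'
#' @return Character vector of length 11.
#' @export
#' @examples
#' canonicalMuscles()
canonicalMuscles <- function() .MUSCLES

#' Walking-environment codes
#'
#' The five environments in label order: flat-ground walking (FGW, label 1),
#' upstairs (US, 2), downstairs (DS, 3), uphill (UW, 4), downhill (DW, 5).
#'
#' @return Character vector of length 5, names are the integer labels.
#' @export
walkingEnvironments <- function() {
  stats::setNames(.ENVIRONMENTS, seq_along(.ENVIRONMENTS))
}

#' Integer label for an environment code
#'
#' @param environment Character vector of environment codes.
#' @return Integer labels in 1..5.
#' @export
#' @examples
#' environmentCode(c("FGW", "DW"))
environmentCode <- function(environment) {
  lab <- match(environment, .ENVIRONMENTS)
  if (anyNA(lab)) {
    stop("unknown environment(s): ",
         paste(setdiff(environment, .ENVIRONMENTS), collapse = ", "),
         "; must be one of ", paste(.ENVIRONMENTS, collapse = ", "))
  }
  lab
}

.checkMuscles <- function(muscles) {
  bad <- setdiff(muscles, .MUSCLES)
  if (length(bad)) {
    stop("unknown muscle name(s): ", paste(bad, collapse = ", "),
         "; canonical set is {", paste(.MUSCLES, collapse = ", "), "}")
  }
  invisible(muscles)
}

# Reorder a muscle subset into canonical order.
.canonicalOrder <- function(muscles) {
  .checkMuscles(muscles)
  .MUSCLES[.MUSCLES %in% muscles]
}
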