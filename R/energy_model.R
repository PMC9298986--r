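#' Read an energy parameter file
#'
#' Loads a simplified nearest-neighbor energy model from a TSV parameter file.
#' The file has three columns (`param`, `key`, `value`): `stack` rows give the
#' stacking energy for a pair of adjacent base pairs keyed `outer:inner` (each
#' written as the 5' base followed by the 3' base of the closing pair), and
#' `misc` rows give the loop-penalty coefficients, the minimum hairpin loop
#' size, the maximum interior-loop side length and the terminal AU/GU penalty.
#' Lines starting with `#` are comments.
#'
#' @param path Path to a parameter TSV. Defaults to the packaged model.
#' @return An object of class `energy_model`: a list with the 6 x 6 `stacks`
#'   matrix (rows = outer pair, columns = inner pair, order
#'   AU, UA, CG, GC, GU, UG) and scalar penalty coefficients.
#' @examples
#' mod <- default_energy_model()
#' mod$stacks["CG", "CG"]
#' @export
read_energy_model <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("param", "key", "value") %in% names(tab)))
  st <- tab[tab$param == "stack", ]
  stacks <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  parts <- strsplit(st$key, ":", fixed = TRUE)
  for (k in seq_along(parts)) {
    stacks[parts[[k]][1], parts[[k]][2]] <- as.numeric(st$value[k])
  }
  if (anyNA(stacks)) stop("energy model: incomplete stack table in ", path)
  if (any(stacks > 0)) stop("energy model: stack energies must be <= 0")
  ms <- tab[tab$param == "misc", ]
  misc <- stats::setNames(as.numeric(ms$value), ms$key)
  need <- c("hairpin_a", "hairpin_b", "bulge_a", "bulge_b", "internal_a",
            "internal_b", "asym_coef", "asym_max", "min_loop", "max_interior",
            "au_end")
  if (!all(need %in% names(misc))) {
    stop("energy model: missing parameters: ",
         paste(setdiff(need, names(misc)), collapse = ", "))
  }
  structure(
    c(list(stacks = stacks), as.list(misc)),
    class = "energy_model",
    source = path
  )
}

.model_cache <- new.env(parent = emptyenv())

#' Default packaged energy model
#'
#' @return The `energy_model` shipped with the package (see
#'   `system.file("extdata", "energy_params.tsv", package = "intronmiR")`).
#' @export
default_energy_model <- function() {
  if (is.null(.model_cache$default)) {
    .model_cache$default <- read_energy_model(
      system.file("extdata", "energy_params.tsv", package = "intronmiR")
    )
  }
  .model_cache$default
}

# Loop penalty helpers -------------------------------------------------------

hairpin_penalty <- function(model, l) {
  ifelse(l < model$min_loop, Inf,
         model$hairpin_a + model$hairpin_b * log(l / model$min_loop))
}

bulge_penalty <- function(model, l) {
  ifelse(l < 1, Inf, model$bulge_a + model$bulge_b * log(l))
}

internal_penalty <- function(model, l1, l2) {
  ifelse(l1 < 1 | l2 < 1, Inf,
         model$internal_a + model$internal_b * log((l1 + l2) / 2) +
           pmin(model$asym_coef * abs(l1 - l2), model$asym_max))
}

# Terminal penalty by pair type name; AU/UA/GU/UG closing pairs pay au_end.
end_penalty <- function(model, pair_name) {
  ifelse(pair_name %in% c("AU", "UA", "GU", "UG"), model$au_end, 0)
}

pair_name_of <- function(b5, b3) {
  nm <- paste0(b5, b3)
  ifelse(nm %in% PAIR_NAMES, nm, NA_character_)
}
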