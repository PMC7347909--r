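# KEGG-style module abundance and module completion ratios.

#' Define a metabolic module
#'
#' A module is an ordered list of components; each component is a set of
#' alternative KO identifiers, any one of which satisfies that step.
#'
#' @param module_id Module label.
#' @param components List of character vectors of KO ids.
#' @param description Optional free-text description.
#' @return An object of class `module_definition`.
#' @export
module_definition <- function(module_id, components, description = NULL) {
  stopifnot(length(components) >= 1,
            all(vapply(components, length, integer(1)) >= 1))
  structure(list(module_id = module_id,
                 components = lapply(components, as.character),
                 description = description),
            class = "module_definition")
}

#' @export
print.module_definition <- function(x, ...) {
  cat("<module_definition> ", x$module_id, ": ", length(x$components),
      " components\n", sep = "")
  invisible(x)
}

#' Module completion ratio (MCR)
#'
#' A component is satisfied when any of its KOs has a nonzero count; the
#' MCR is `100 * satisfied / total`, rounded half-up to an integer percent.
#' With a matrix input, one MCR per sample column is returned.
#'
#' @param module A [module_definition()].
#' @param ko_counts Named numeric vector of KO counts for one sample, or a
#'   KO x sample matrix with KO row names.
#' @return Numeric MCR percent (vector for matrix input). Errors if the
#'   module references KOs absent from the table, listing them.
#' @export
#' @examples
#' m <- module_definition("toy", list("K1", "K2"))
#' mcr(m, c(K1 = 5, K2 = 0))
mcr <- function(module, ko_counts) {
  stopifnot(inherits(module, "module_definition"))
  kos <- unique(unlist(module$components))
  have <- if (is.matrix(ko_counts)) rownames(ko_counts) else names(ko_counts)
  missing_kos <- setdiff(kos, have)
  if (length(missing_kos)) {
    stop("module '", module$module_id, "' references KOs absent from the ",
         "table: ", paste(missing_kos, collapse = ", "), call. = FALSE)
  }
  one <- function(counts) {
    if (any(counts < 0)) stop("KO counts must be nonnegative", call. = FALSE)
    sat <- vapply(module$components,
                  function(comp) any(counts[comp] > 0), logical(1))
    round_half_up(100 * sum(sat) / length(sat))
  }
  if (is.matrix(ko_counts)) {
    apply(ko_counts, 2, function(col) one(stats::setNames(col, rownames(ko_counts))))
  } else {
    one(ko_counts)
  }
}

#' Module abundance, raw and ribosomal-protein normalized
#'
#' `abundance_raw` sums the counts of every KO in the module;
#' `abundance_norm` divides by the summed counts of the ribosomal-protein
#' KOs (the normalization reference). A zero ribosomal total flags the
#' normalized value as undefined (`NA`).
#'
#' @param module A [module_definition()].
#' @param ko_counts Named KO count vector for one sample.
#' @param ribosomal_ko_counts Named count vector of ribosomal-protein KOs
#'   for the same sample.
#' @return List with `abundance_raw` and `abundance_norm`.
#' @export
module_abundance <- function(module, ko_counts, ribosomal_ko_counts) {
  kos <- unique(unlist(module$components))
  missing_kos <- setdiff(kos, names(ko_counts))
  if (length(missing_kos)) {
    stop("module '", module$module_id, "' references KOs absent from the ",
         "table: ", paste(missing_kos, collapse = ", "), call. = FALSE)
  }
  raw <- sum(ko_counts[kos])
  rib <- sum(ribosomal_ko_counts)
  list(abundance_raw = raw,
       abundance_norm = if (rib > 0) raw / rib else NA_real_)
}

#' Standardize a module x sample abundance matrix
#'
#' Row-wise z-scores with the population standard deviation (divisor `n`),
#' the standardization used for module-abundance heatmaps. Constant rows
#' become all zeros with a warning.
#'
#' @param mat Numeric matrix (modules x samples, >= 2 columns).
#' @return Matrix of the same shape with row mean 0 and population SD 1
#'   (or all-zero constant rows).
#' @export
standardize_modules <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  out <- t(apply(mat, 1, function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) {
      rep(0, length(x))
    } else {
      (x - mean(x)) / s
    }
  }))
  if (any(apply(mat, 1, function(x) sqrt(mean((x - mean(x))^2))) == 0)) {
    warning("constant module row(s) standardized to zero", call. = FALSE)
  }
  dimnames(out) <- dimnames(mat)
  out
}

#' Read module definitions from JSON
#'
#' Expected layout: an array of `{module_id, components: [[KO, ...], ...]}`
#' objects.
#'
#' @param path JSON path.
#' @return List of [module_definition()] objects.
#' @export
read_module_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(m) {
    module_definition(m$module_id,
                      lapply(m$components, function(c) unlist(c)),
                      description = m$description)
  })
}

#' Write module definitions to JSON
#' @param modules List of [module_definition()] objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_module_json <- function(modules, path) {
  out <- lapply(modules, function(m) {
    list(module_id = m$module_id, description = m$description,
         components = m$components)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
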