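## Structural-alert screening (PAINS, Brenk) and leadlikeness.
##
## Catalogs are plain-text files of SMARTS patterns with tab-separated
## descriptions.  The packaged catalogs are count-preserving synthetic
## stand-ins (see their headers): a core of genuine published alert
## motifs plus inert filler patterns, because the original catalog files
## cannot be redistributed from this build environment.  Any user catalog
## in the same format can be screened.

#' Load a SMARTS catalog
#'
#' Reads a catalog file (one \code{SMARTS<TAB>description} entry per
#' line, \code{#} comments allowed), optionally validates that every
#' pattern compiles in the SMARTS engine, and checks the entry count.
#'
#' @param path Catalog file.
#' @param expected_count Expected number of entries (error if different);
#'   NULL to skip the check.
#' @param validate Compile-check every pattern (default TRUE).
#' @param name Catalog name; defaults to the file name.
#' @return Object of class \code{adm_catalog}: data.frame with
#'   \code{pattern} and \code{description} plus a \code{name} attribute.
#' @export
load_catalog <- function(path, expected_count = NULL, validate = TRUE,
                         name = NULL) {
  if (!file.exists(path)) {
    adm_error("adm_io", paste0("catalog file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^[[:space:]]*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pattern <- vapply(parts, `[[`, "", 1L)
  description <- vapply(parts, function(p) {
    if (length(p) >= 2L) p[[2L]] else ""
  }, "")
  if (!is.null(expected_count) && length(pattern) != expected_count) {
    adm_error("adm_count_mismatch",
              sprintf("catalog %s: %d entries, expected %d",
                      path, length(pattern), expected_count))
  }
  if (validate) {
    probe <- probe_sdfset()
    for (k in seq_along(pattern)) {
      ok <- tryCatch({
        ob_quiet(ChemmineR::smartsSearchOB(probe, pattern[k],
                                           uniqueMatches = TRUE))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) {
        adm_error("adm_bad_pattern",
                  sprintf("catalog %s line %d: SMARTS does not compile: '%s'",
                          path, lineno[k], pattern[k]))
      }
    }
  }
  structure(
    data.frame(pattern = pattern, description = description,
               stringsAsFactors = FALSE),
    name = name %||% sub("\\.[^.]*$", "", basename(path)),
    class = c("adm_catalog", "data.frame")
  )
}

## one-molecule SDF used for SMARTS compile probing (cached; a bonded
## molecule — the SMARTS engine rejects atom-only structures)
probe_sdfset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- as_sdfset(adm_molecule("CCO", "probe"))
    }
    cache
  }
})

#' Packaged alert catalogs
#'
#' Convenience loaders for the packaged pan-assay-interference (481
#' entries) and structural-alert (105 entries) catalogs.  Both are
#' synthetic count-preserving stand-ins built around a core of genuine
#' published alert motifs; see the catalog file headers.
#' @return \code{adm_catalog}.
#' @export
pains_catalog <- function() {
  load_catalog(system.file("extdata", "pains_synthetic.smarts",
                           package = "admetk"),
               expected_count = 481L, validate = FALSE, name = "PAINS")
}

#' @rdname pains_catalog
#' @export
brenk_catalog <- function() {
  load_catalog(system.file("extdata", "brenk_synthetic.smarts",
                           package = "admetk"),
               expected_count = 105L, validate = FALSE, name = "Brenk")
}

#' Screen a molecule against a SMARTS catalog
#'
#' Every pattern with at least one substructure match is reported once,
#' with its match count, in catalog order (deterministic).
#'
#' @param mol An \code{adm_molecule}.
#' @param catalog \code{adm_catalog}.
#' @return data.frame with \code{pattern}, \code{description},
#'   \code{n_matches} (one row per hit pattern; zero rows when clean).
#' @export
alert_screen <- function(mol, catalog) {
  stopifnot(inherits(mol, "adm_molecule"), inherits(catalog, "adm_catalog"))
  sdf <- as_sdfset(mol)
  hits <- integer(nrow(catalog))
  for (k in seq_len(nrow(catalog))) {
    hits[k] <- tryCatch(
      as.integer(ob_quiet(ChemmineR::smartsSearchOB(
        sdf, catalog$pattern[k], uniqueMatches = TRUE))[[1]]),
      error = function(e) 0L)
  }
  out <- catalog[hits > 0L, , drop = FALSE]
  out$n_matches <- hits[hits > 0L]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Leadlikeness filter
#'
#' Physicochemical window for optimization starting points: MW in
#' [250, 350], lipophilicity at most 3.5, at most 7 rotatable bonds.
#' Leads are required to be smaller and less hydrophobic than drug-like
#' molecules.
#'
#' @param descriptors \code{adm_descriptors}.
#' @param logp_value Lipophilicity (external atomistic slot or WLOGP).
#' @param rules Threshold configuration.
#' @return \code{adm_filter}.
#' @export
leadlikeness <- function(descriptors, logp_value = descriptors$WLOGP,
                         rules = druglikeness_rules()) {
  rl <- rules$leadlikeness
  v <- character(0)
  if (descriptors$MW < rl$mw[1]) v <- c(v, sprintf("MW < %g", rl$mw[1]))
  if (descriptors$MW > rl$mw[2]) v <- c(v, sprintf("MW > %g", rl$mw[2]))
  if (logp_value > rl$xlogp_max)
    v <- c(v, sprintf("XLOGP > %g", rl$xlogp_max))
  if (descriptors$rotatable_bonds > rl$rotatable_max)
    v <- c(v, sprintf("rotatable bonds > %g", rl$rotatable_max))
  filter_result("Leadlikeness", v)
}
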