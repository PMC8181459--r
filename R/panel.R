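# Locus panel configuration and allele-designation handling.
#
# Allele designations are kept as exact character strings ("14", "19.1")
# throughout; numeric conversion happens only inside distance kernels, so a
# microvariant never prints as 19.099999....

.ystr_error <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("ystr_", class), "ystr_error")))
}

#' Define a Y-STR locus panel
#'
#' A panel names the loci of a haplotype table, flags which of them are
#' multi-copy (reported as an unordered allele multiset, like DYS385a/b), and
#' which enter repeat-count distance computations.
#'
#' @param loci Character vector of locus names, in reporting order.
#' @param multicopy_loci Subset of `loci` treated as unordered allele
#'   multisets. Default: none.
#' @param distance_loci Subset of `loci` used by squared repeat-count
#'   distances. Default: all single-copy loci (multi-copy loci lack copy
#'   orthology, so their repeat differences are not well defined).
#' @return An object of class `ystr_panel`.
#' @seealso [ppy23_panel()] for the PowerPlex Y23 default.
#' @export
ystr_panel <- function(loci, multicopy_loci = character(),
                       distance_loci = setdiff(loci, multicopy_loci)) {
  loci <- as.character(loci)
  if (anyDuplicated(loci))
    .ystr_error("invalid_parameter", "duplicated locus names in panel")
  if (!all(multicopy_loci %in% loci))
    .ystr_error("invalid_parameter", "multicopy_loci must be a subset of loci")
  if (!all(distance_loci %in% loci))
    .ystr_error("invalid_parameter", "distance_loci must be a subset of loci")
  structure(list(loci = loci,
                 multicopy_loci = as.character(multicopy_loci),
                 distance_loci = as.character(distance_loci)),
            class = "ystr_panel")
}

#' The PowerPlex Y23 locus panel
#'
#' The 23 Y-STRs of the Promega PowerPlex Y23 system: the 17 Yfiler loci
#' (with DYS385a/b held as one combined multi-copy locus, `DYS385ab`) plus
#' six additional highly discriminating loci. DYS389II is used exactly as
#' reported by the kit (no subtraction of DYS389I), and DYS385ab is excluded
#' from repeat-count distances by default.
#'
#' @return An object of class `ystr_panel` with 22 columns covering 23 Y-STRs.
#' @export
ppy23_panel <- function() {
  ystr_panel(
    loci = c("DYS19", "DYS385ab", "DYS389I", "DYS389II", "DYS390", "DYS391",
             "DYS392", "DYS393", "DYS437", "DYS438", "DYS439", "DYS448",
             "DYS456", "DYS458", "DYS635", "YGATAH4", "DYS481", "DYS533",
             "DYS549", "DYS570", "DYS576", "DYS643"),
    multicopy_loci = "DYS385ab"
  )
}

#' @export
print.ystr_panel <- function(x, ...) {
  cat("Y-STR panel:", length(x$loci), "loci\n")
  cat("  loci:", paste(x$loci, collapse = ", "), "\n")
  if (length(x$multicopy_loci))
    cat("  multi-copy:", paste(x$multicopy_loci, collapse = ", "), "\n")
  cat("  distance loci:", length(x$distance_loci), "\n")
  invisible(x)
}

#' Read or write a panel configuration file
#'
#' Panels are stored as small YAML files with keys `loci`, `multicopy_loci`
#' and `distance_loci` (the latter two optional).
#'
#' @param path File path.
#' @return `read_panel_config()` returns a `ystr_panel`;
#'   `write_panel_config()` returns `path` invisibly.
#' @export
read_panel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$loci))
    .ystr_error("invalid_parameter", "panel config %s lacks a 'loci' key", path)
  mc <- if (is.null(cfg$multicopy_loci)) character() else cfg$multicopy_loci
  if (is.null(cfg$distance_loci)) {
    ystr_panel(cfg$loci, mc)
  } else {
    ystr_panel(cfg$loci, mc, cfg$distance_loci)
  }
}

#' @rdname read_panel_config
#' @param panel A `ystr_panel`.
#' @export
write_panel_config <- function(panel, path) {
  stopifnot(inherits(panel, "ystr_panel"))
  yaml::write_yaml(list(loci = panel$loci,
                        multicopy_loci = panel$multicopy_loci,
                        distance_loci = panel$distance_loci), path)
  invisible(path)
}

# --- allele designations ------------------------------------------------

# Valid designations: positive integer repeat count, optional microvariant
# fraction .1/.2/.3 (e.g. "19.1" = 19 repeats + 1 extra base).
.allele_ok <- function(x) {
  grepl("^[0-9]+(\\.[123])?$", x) & x != "0" & !grepl("^0\\.", x)
}

# Parse one cell into canonical form, or NA for missing ("", "0", NA).
# Multi-copy cells may join values with "," or "-"; values are sorted
# ascending numerically and re-joined with ",".
.parse_cell <- function(cell, locus, multicopy) {
  cell <- trimws(as.character(cell))
  if (is.na(cell) || cell == "" || cell == "0") return(NA_character_)
  if (multicopy) {
    parts <- trimws(strsplit(cell, "[,-]")[[1]])
    if (!length(parts) || !all(.allele_ok(parts)))
      .ystr_error("bad_allele", "unparsable allele '%s' at locus %s", cell, locus)
    paste(parts[order(as.numeric(parts), parts)], collapse = ",")
  } else {
    if (!.allele_ok(cell))
      .ystr_error("bad_allele", "unparsable allele '%s' at locus %s", cell, locus)
    cell
  }
}

# Numeric value(s) of a canonical cell; multi-copy cells give a vector.
.cell_numeric <- function(cell) {
  if (is.na(cell)) return(NA_real_)
  as.numeric(strsplit(cell, ",", fixed = TRUE)[[1]])
}
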