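#' Load the phantom constraint tables
#'
#' Reads the structured text configuration holding the geometric constraint
#' tables of the head phantom: per-element centre/size/tilt ranges, the
#' circumference and axes-ratio limits, the global area-fraction limits, and
#' the sampling settings. The package ships the published constraint set as
#' its default; users can copy and edit the file to change ranges without
#' touching code.
#'
#' @param path Path to a YAML constraint file; `NULL` loads the packaged
#'   default.
#' @return A validated constraint table object of class `cceit_constraints`.
#' @export
#' @examples
#' tab <- load_constraint_tables()
#' names(tab$elements)
load_constraint_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "head_constraints.yaml", package = "cceit")
  }
  if (!file.exists(path)) stop("constraint file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_constraint_tables(cfg)
}

validate_constraint_tables <- function(cfg) {
  need <- c("image", "head", "midline", "elements", "satellites",
            "area_constraints", "sampling")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0)
    stop("constraint config missing sections: ", paste(missing, collapse = ", "))
  chk_range <- function(r, where) {
    if (!is.list(r) || is.null(r$mean) || is.null(r$hr))
      stop("constraint entry ", where, " needs mean and hr")
    if (r$hr < 0) stop("negative half-range in ", where)
    r
  }
  elems <- c("inner", "ldown", "lup", "rdown", "rup", "center_csf")
  if (!setequal(names(cfg$elements), elems))
    stop("elements must be exactly: ", paste(elems, collapse = ", "))
  for (nm in names(cfg$elements)) {
    el <- cfg$elements[[nm]]
    for (f in c("center_x", "center_y", "size_x", "size_y", "tilt"))
      chk_range(el[[f]], paste0(nm, "$", f))
  }
  sats <- c("csf1", "csf2", "csf3", "csf4")
  if (!setequal(names(cfg$satellites), sats))
    stop("satellites must be exactly: ", paste(sats, collapse = ", "))
  for (nm in names(cfg$satellites)) {
    el <- cfg$satellites[[nm]]
    for (f in c("axis_angle", "shift", "size_x", "size_y", "tilt"))
      chk_range(el[[f]], paste0(nm, "$", f))
  }
  for (f in c("brain_fraction", "csf_fraction", "rest_fraction",
              "hemisphere_ratio"))
    chk_range(cfg$area_constraints[[f]], paste0("area_constraints$", f))
  for (f in c("shift_x", "shift_y", "tilt"))
    chk_range(cfg$midline[[f]], paste0("midline$", f))
  if (cfg$head$semi_x <= 0 || cfg$head$semi_y <= 0)
    stop("head semiaxes must be positive")
  cfg$sampling$law <- match.arg(cfg$sampling$law %||% "truncnorm",
                                c("truncnorm", "uniform"))
  cfg$sampling$max_attempts <- as.integer(cfg$sampling$max_attempts %||% 10000)
  cfg$sampling$local_attempts <- as.integer(cfg$sampling$local_attempts %||% 1000)
  class(cfg) <- "cceit_constraints"
  cfg
}

#' @export
print.cceit_constraints <- function(x, ...) {
  cat("<cceit_constraints>\n")
  cat("  head outline:", x$head$semi_x, "x", x$head$semi_y, "mm semiaxes\n")
  cat("  elements:", paste(names(x$elements), collapse = ", "), "\n")
  cat("  satellites:", paste(names(x$satellites), collapse = ", "), "\n")
  cat("  image extent:", x$image$extent_mm, "mm,", x$image$target_px, "px\n")
  invisible(x)
}
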