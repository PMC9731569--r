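#' Tool configuration
#'
#' A tool configuration describes how one predictor's scores are compared
#' against a decision threshold: the direction of pathogenicity (whether
#' high or low scores indicate a damaging variant), whether the threshold
#' value itself counts as a pathogenic call, whether scores live on the
#' unit interval (which fixes the threshold grid), and the tool category.
#'
#' @param name Tool name (must match a score-matrix column).
#' @param direction `"higher_pathogenic"` or `"lower_pathogenic"`.
#' @param pathogenic_inclusive Logical; `TRUE` when a score exactly equal to
#'   the threshold is called pathogenic (a `>=`/`<=` comparator rather than
#'   `>`/`<`).
#' @param bounded_unit_interval Logical; `TRUE` when scores are confined to
#'   `[0, 1]`.
#' @param category `"general"`, `"splicing"` or `"conservation"`.
#' @return A `tool_config` object (a named list).
#' @examples
#' tool_config("REVEL", "higher_pathogenic", FALSE, TRUE, "general")
#' @export
tool_config <- function(name,
                        direction = c("higher_pathogenic", "lower_pathogenic"),
                        pathogenic_inclusive = FALSE,
                        bounded_unit_interval = FALSE,
                        category = c("general", "splicing", "conservation")) {
  direction <- match.arg(direction)
  category <- match.arg(category)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.logical(pathogenic_inclusive), length(pathogenic_inclusive) == 1L,
            is.logical(bounded_unit_interval), length(bounded_unit_interval) == 1L)
  structure(list(name = name,
                 direction = direction,
                 pathogenic_inclusive = pathogenic_inclusive,
                 bounded_unit_interval = bounded_unit_interval,
                 category = category),
            class = "tool_config")
}

#' @export
print.tool_config <- function(x, ...) {
  cmp <- comparator_string(x)
  cat(sprintf("<tool_config> %s  (pathogenic if score %s t; %s; %s)\n",
              x$name, cmp,
              if (x$bounded_unit_interval) "scores in [0,1]" else "unbounded scores",
              x$category))
  invisible(x)
}

comparator_string <- function(tool) {
  if (tool$direction == "higher_pathogenic") {
    if (tool$pathogenic_inclusive) ">=" else ">"
  } else {
    if (tool$pathogenic_inclusive) "<=" else "<"
  }
}

#' Default predictor configuration
#'
#' The shipped configuration transcribes the comparators used in the
#' evaluation of 31 predictors on globin gene variants: FATHMM, SIFT, LRT
#' and PROVEAN call low scores pathogenic; every other tool calls high
#' scores pathogenic. Inclusivity follows each tool's printed comparator
#' (e.g. BayesDel `>=`, CADD `>`, FATHMM `<=`, SIFT `<`). The configuration
#' is a default, not a constraint: pass your own list of [tool_config()]
#' objects (or a YAML file via [read_tool_config()]) to override it.
#'
#' @return Named list of `tool_config` objects.
#' @examples
#' cfg <- default_tool_config()
#' cfg[["CADD"]]
#' @export
default_tool_config <- function() {
  path <- system.file("extdata", "tools.yaml", package = "hbcalib")
  read_tool_config(path)
}

#' Read tool configurations from YAML
#'
#' The YAML file maps tool names to fields `direction`,
#' `pathogenic_inclusive`, `bounded_unit_interval` and `category`;
#' omitted fields take the [tool_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return Named list of `tool_config` objects.
#' @export
read_tool_config <- function(path) {
  if (!file.exists(path)) stop("tool configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("tool configuration file is empty: ", path)
  out <- lapply(names(raw), function(nm) {
    f <- raw[[nm]]
    tool_config(name = nm,
                direction = f$direction %||% "higher_pathogenic",
                pathogenic_inclusive = isTRUE(f$pathogenic_inclusive),
                bounded_unit_interval = isTRUE(f$bounded_unit_interval),
                category = f$category %||% "general")
  })
  names(out) <- names(raw)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_tool_config_list <- function(tools) {
  if (inherits(tools, "tool_config")) tools <- list(tools)
  stopifnot(is.list(tools), all(vapply(tools, inherits, logical(1), "tool_config")))
  names(tools) <- vapply(tools, `[[`, character(1), "name")
  tools
}
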