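# Component libraries: named collections of programs, stored as XML
# (primary dialect, XSD shipped in inst/extdata) or JSON.  Each component
# embeds its behaviour as DSL text.
#
#   <library version="1">
#     <component name="Q1"><gubs>LacI o-> !TetR_lite</gubs></component>
#     ...
#   </library>

LIBRARY_SCHEMA_VERSION <- "1"

#' Create a component library
#'
#' @param components Named list of [gubs_program()]s (names unique).
#'   Components are macro-expanded and validated on construction.
#' @param source Optional provenance string (file path).
#' @return Object of class `gubs_library`.
#' @export
gubs_library <- function(components = list(), source = NA_character_) {
  nms <- names(components)
  if (length(components) && (is.null(nms) || any(!nzchar(nms))))
    stop("components must be named", call. = FALSE)
  if (anyDuplicated(nms))
    stop("duplicate component name: ", nms[duplicated(nms)][1],
         call. = FALSE)
  components <- lapply(components, function(p) {
    stopifnot(inherits(p, "gubs_program"))
    expand_macros(p)
  })
  structure(list(components = components, source = source),
            class = "gubs_library")
}

#' @export
print.gubs_library <- function(x, ...) {
  cat(sprintf("component library (%d components)\n", length(x$components)))
  for (nm in names(x$components))
    cat(sprintf("  %s: %d rule(s)\n", nm, length(x$components[[nm]]$rules)))
  invisible(x)
}

#' @export
length.gubs_library <- function(x) length(x$components)

guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("xml", "json")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xml", "json")) ext
  else stop("cannot guess library format from extension '", ext, "'",
            call. = FALSE)
}

#' Read a component library
#'
#' XML documents are validated against the shipped XSD; both formats get
#' element-level structural checks, and every component's DSL text is
#' parsed, macro-expanded and validated.
#'
#' @param path File path.
#' @param format `"xml"` or `"json"`; guessed from the extension when
#'   `NULL`.
#' @return A [gubs_library()].
#' @export
read_library <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- guess_format(path, format)
  comps <- if (format == "xml") read_library_xml(path)
           else read_library_json(path)
  nms <- vapply(comps, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate component name: ", nms[duplicated(nms)][1],
         call. = FALSE)
  programs <- lapply(comps, function(cc)
    tryCatch(parse_program(cc$text),
             error = function(e) stop("component '", cc$name, "': ",
                                      conditionMessage(e), call. = FALSE)))
  names(programs) <- nms
  gubs_library(programs, source = path)
}

read_library_xml <- function(path) {
  doc <- xml2::read_xml(path)
  xsd_path <- system.file("extdata", "gubs-library.xsd", package = "gubsc")
  if (nzchar(xsd_path)) {
    ok <- xml2::xml_validate(doc, xml2::read_xml(xsd_path))
    if (!ok)
      stop("library does not validate against the schema: ",
           paste(attr(ok, "errors"), collapse = "; "), call. = FALSE)
  }
  if (xml2::xml_name(doc) != "library")
    stop("root element must be <library>", call. = FALSE)
  lapply(xml2::xml_find_all(doc, "./component"), function(node) {
    nm <- xml2::xml_attr(node, "name")
    if (is.na(nm) || !nzchar(nm))
      stop("<component> element without a name attribute", call. = FALSE)
    g <- xml2::xml_find_first(node, "./gubs")
    if (inherits(g, "xml_missing"))
      stop("component '", nm, "' lacks a <gubs> element", call. = FALSE)
    list(name = nm, text = xml2::xml_text(g))
  })
}

read_library_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(doc) || is.null(doc$components))
    stop("JSON library requires a 'components' array", call. = FALSE)
  lapply(doc$components, function(cc) {
    if (is.null(cc$name) || !nzchar(cc$name))
      stop("JSON component without a 'name' field", call. = FALSE)
    if (is.null(cc$gubs))
      stop("component '", cc$name, "' lacks a 'gubs' field", call. = FALSE)
    list(name = cc$name, text = cc$gubs)
  })
}

#' Write a component library
#'
#' @param lib A [gubs_library()].
#' @param path Output path.
#' @param format `"xml"` or `"json"`; guessed from the extension when
#'   `NULL`.  `read_library(write_library(lib, path))` is structurally
#'   equal to `lib`.
#' @return The path, invisibly.
#' @export
write_library <- function(lib, path, format = NULL) {
  stopifnot(inherits(lib, "gubs_library"))
  format <- guess_format(path, format)
  if (format == "xml") {
    doc <- xml2::xml_new_root("library", version = LIBRARY_SCHEMA_VERSION)
    for (nm in names(lib$components)) {
      node <- xml2::xml_add_child(doc, "component", name = nm)
      g <- xml2::xml_add_child(node, "gubs")
      xml2::xml_text(g) <- serialize_program(lib$components[[nm]])
    }
    xml2::write_xml(doc, path)
  } else {
    doc <- list(schema_version = LIBRARY_SCHEMA_VERSION,
                components = lapply(names(lib$components), function(nm)
                  list(name = nm,
                       gubs = serialize_program(lib$components[[nm]]))))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Built-in example programs and library
#'
#' Three worked objects used throughout the documentation and tests:
#'
#' * `repressilator_goal`: the three-gene mutual-inhibition ring as a
#'   design goal -- three persistent rules with negated effects, two
#'   variable genes `g1`, `g2` and the named part `TetR_lite`.
#' * `repressilator_lib5`: a small *synthetic* five-component repression
#'   library (LacI/TetR/CI ring parts plus a GFP-targeting repressor and
#'   an unrelated AraC part) exercising every branch of the pre-selection
#'   filters; also shipped as
#'   `extdata/repressilator_lib5_synthetic.{xml,json}`.
#' * `lambda_switch`: the two-gene lysis/lysogeny toggle of phage lambda
#'   (Cro and CI with `low < high` activity levels, two strong-inhibition
#'   macros, three observation spots).
#'
#' @return Named list with the three objects.
#' @export
gubs_fixtures <- function() {
  goal <- parse_program(c(
    "g1 o-> !g2",
    "g2 o-> !TetR_lite",
    "TetR_lite o-> !g1"))
  lib <- gubs_library(list(
    Q1 = parse_program("LacI o-> !TetR_lite"),
    Q2 = parse_program("CI o-> !LacI"),
    Q3 = parse_program("TetR_lite o-> !CI"),
    Q4 = parse_program("TetR_lite o-> !GFP"),
    Q5 = parse_program("AraC o-> !GFP")),
    source = "builtin:repressilator_lib5")
  lambda <- parse_program(c(
    "Cro:{low<high}",
    "CI:{low<high}",
    "Cro(low) -- CI(high)",
    "CI(low) -- Cro(high)",
    "obs_1:: Cro(high)",
    "obs_2:: Cro(low)",
    "obs_3:: CI(low)"))
  list(repressilator_goal = goal,
       repressilator_lib5 = lib,
       lambda_switch = lambda)
}
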