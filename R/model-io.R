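# Plain-text serialization of model specifications.
#
# Format (one directive per line, '#' comments ignored):
#
#   microtumor-model 1
#   variant M2
#   hill 1
#   [geometry]      r_core / r_inner / r_outer / v_extracellular entries
#   [clamped]       species ids held constant
#   [constants]     <id> <value>, full double precision
#   [rules]         <id> <kind> A + B -> C + D @ <constant id>
#                   optionally '! <inhibitor species> <K_I id>'
#                   '0' denotes an empty side (degradation)
#   [decay]         <species> @ <constant id>
#
# write_model() emits sections in a fixed order so that
# read_model(write_model(x)) reproduces the specification exactly.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Serialize a model specification to a plain-text file
#'
#' Writes the geometry, clamped species, rate constants (full double
#' precision), reaction rules and decay entries of a model to a sectioned
#' plain-text file that [read_model()] parses back into an identical
#' specification.
#'
#' @param spec an [`mt_model`][build_model] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(spec, path) {
  validate_model(spec)
  fmt_rule <- function(r) {
    side <- function(s) if (length(s)) paste(s, collapse = " + ") else "0"
    line <- sprintf("%s %s %s -> %s @ %s", r$id, r$kind, side(r$reactants),
                    side(r$products), r$k)
    if (!is.null(r$inhibitor))
      line <- sprintf("%s ! %s %s", line, r$inhibitor$species,
                      r$inhibitor$k_i)
    line
  }
  g <- spec$geometry
  lines <- c(
    "microtumor-model 1",
    paste("variant", spec$variant),
    paste("hill", fmt_num(spec$hill)),
    "[geometry]",
    paste("r_core", fmt_num(g$r_core)),
    paste("r_inner", fmt_num(g$r_inner)),
    paste("r_outer", fmt_num(g$r_outer)),
    paste("v_extracellular", fmt_num(g$v_extracellular)),
    "[clamped]",
    spec$clamped,
    "[constants]",
    sprintf("%s %s", names(spec$rate_constants),
            vapply(spec$rate_constants, fmt_num, character(1))),
    "[rules]",
    vapply(spec$rules, fmt_rule, character(1)),
    "[decay]",
    sprintf("%s @ %s", names(spec$decay), unname(spec$decay))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a model specification from a plain-text file
#'
#' Parses the sectioned format written by [write_model()] and returns a
#' validated model. Malformed lines, unknown species or compartments, and
#' rate constants referenced but not defined are errors that name the
#' offending line.
#'
#' @param path file path.
#' @return An [`mt_model`][build_model] object.
#' @export
read_model <- function(path) {
  raw <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", raw)
  keep <- which(nzchar(trimws(lines)))
  lines <- trimws(lines[keep])
  lineno <- keep
  perr <- function(i, msg) stop("parse error at line ", lineno[i], ": ", msg,
                                " [", lines[i], "]", call. = FALSE)
  if (!length(lines) || !grepl("^microtumor-model\\s+1$", lines[1]))
    stop("not a microtumor-model v1 file", call. = FALSE)
  section <- ""
  variant <- NULL; hill <- 1
  geom_kv <- c(); clamped <- character(0)
  constants <- numeric(0); rules <- list(); decay <- c()
  parse_side <- function(s, i) {
    s <- trimws(s)
    if (s == "0") return(character(0))
    sp <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    for (x in sp) if (is.null(mt_split_species(x)) ||
                      !x %in% mt_state_ids)
      perr(i, paste0("unknown species '", x, "'"))
    sp
  }
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (grepl("^\\[", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% c("geometry", "clamped", "constants", "rules",
                          "decay"))
        perr(i, "unknown section")
      next
    }
    if (section == "") {
      kv <- strsplit(ln, "\\s+")[[1]]
      if (length(kv) != 2L) perr(i, "expected 'key value'")
      if (kv[1] == "variant") variant <- kv[2]
      else if (kv[1] == "hill") hill <- as.numeric(kv[2])
      else perr(i, "unknown header key")
    } else if (section == "geometry") {
      kv <- strsplit(ln, "\\s+")[[1]]
      if (length(kv) != 2L || is.na(as.numeric(kv[2])))
        perr(i, "expected 'key number'")
      geom_kv[kv[1]] <- as.numeric(kv[2])
    } else if (section == "clamped") {
      if (!ln %in% mt_state_ids) perr(i, "unknown clamped species")
      clamped <- c(clamped, ln)
    } else if (section == "constants") {
      kv <- strsplit(ln, "\\s+")[[1]]
      if (length(kv) != 2L || is.na(suppressWarnings(as.numeric(kv[2]))))
        perr(i, "expected '<id> <value>'")
      if (kv[1] %in% names(constants))
        perr(i, paste0("duplicate rate constant '", kv[1], "'"))
      constants[kv[1]] <- as.numeric(kv[2])
    } else if (section == "rules") {
      m <- regmatches(ln, regexec(
        "^(\\S+)\\s+(\\S+)\\s+(.*?)\\s*->\\s*(.*?)\\s*@\\s*(\\S+)(\\s*!\\s*(\\S+)\\s+(\\S+))?$",
        ln))[[1]]
      if (length(m) == 0L) perr(i, "malformed rule")
      kind <- m[3]
      if (!kind %in% c("transport", "production", "catalytic_production",
                       "degradation", "source"))
        perr(i, paste0("unknown rule kind '", kind, "'"))
      inhib <- NULL
      if (nzchar(m[7])) inhib <- list(species = m[8], k_i = m[9])
      rules[[length(rules) + 1L]] <- mt_rule(
        id = m[2], kind = kind,
        reactants = parse_side(m[4], i), products = parse_side(m[5], i),
        k = m[6], inhibitor = inhib)
    } else if (section == "decay") {
      m <- regmatches(ln, regexec("^(\\S+)\\s*@\\s*(\\S+)$", ln))[[1]]
      if (length(m) == 0L) perr(i, "malformed decay entry")
      if (!m[2] %in% mt_state_ids) perr(i, "unknown species in decay entry")
      decay[m[2]] <- m[3]
    }
  }
  if (is.null(variant) || !variant %in% c("M1", "M2"))
    stop("file must declare variant M1 or M2", call. = FALSE)
  need_geom <- c("r_core", "r_inner", "r_outer", "v_extracellular")
  if (!all(need_geom %in% names(geom_kv)))
    stop("geometry section incomplete: need ",
         paste(setdiff(need_geom, names(geom_kv)), collapse = ", "),
         call. = FALSE)
  geometry <- build_geometry(geom_kv[["r_core"]], geom_kv[["r_inner"]],
                             geom_kv[["r_outer"]],
                             v_extracellular = geom_kv[["v_extracellular"]])
  spec <- structure(
    list(variant = variant, geometry = geometry, rules = rules,
         rate_constants = constants, decay = decay, clamped = clamped,
         hill = hill),
    class = "mt_model"
  )
  validate_model(spec)
  spec
}
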