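# Bookmarkable view-state codec. The encoding is an order-insensitive
# key=value&... parameter string:
#
#   genomes=a,b,c            displayed genomes, track order (required)
#   mode=free|locked|aligned-on:<canonical id>
#   ref=<genome>             optional reference genome
#   seg.<genome>=tok[,tok]   tok = chrom:start..end, trailing "r" marks a
#                            flipped segment; "." is a placeholder
#   filter.biotypes=a,b      filter.minlen=N  filter.maxlen=N
#   filter.differential=1    filter.selected=1
#   sel=id1,id2              selected canonical ids
#   list=<name>:<mode>       gene-list mode (highlight|restrict|exclude)
#
# decode(encode(s)) is exact for every valid state.

encode_segment <- function(seg) {
  if (seg$placeholder) return(".")
  paste0(seg$chromosome, ":", fmt_bp(seg$start), "..", fmt_bp(seg$end),
         if (seg$flipped) "r" else "")
}

decode_segment <- function(tok, genome) {
  if (tok == ".") return(placeholder_segment(genome))
  flipped <- grepl("r$", tok)
  if (flipped) tok <- sub("r$", "", tok)
  m <- regmatches(tok, regexec("^([^:]+):([0-9]+)\\.\\.([0-9]+)$", tok))[[1]]
  if (length(m) != 4L)
    stop("view-state parse error: malformed segment '", tok, "'")
  region_segment(genome, m[2], as.numeric(m[3]), as.numeric(m[4]), flipped)
}

#' Encode a view state as a bookmarkable parameter string
#'
#' @param state A [view_state()].
#' @return A `key=value&...` string; see [decode_view_state()] for the
#'   grammar.
#' @export
encode_view_state <- function(state) {
  parts <- c(paste0("genomes=", paste(state$genomes, collapse = ",")),
             paste0("mode=", state$mode))
  if (!is.na(state$reference %||% NA_character_))
    parts <- c(parts, paste0("ref=", state$reference))
  for (g in state$genomes) {
    toks <- vapply(state$segments[[g]], encode_segment, "")
    parts <- c(parts, paste0("seg.", g, "=", paste(toks, collapse = ",")))
  }
  fs <- state$filters
  if (!is.null(fs$biotypes))
    parts <- c(parts, paste0("filter.biotypes=", paste(fs$biotypes, collapse = ",")))
  if (!is.null(fs$min_length))
    parts <- c(parts, paste0("filter.minlen=", fmt_bp(fs$min_length)))
  if (!is.null(fs$max_length))
    parts <- c(parts, paste0("filter.maxlen=", fmt_bp(fs$max_length)))
  if (isTRUE(fs$differential)) parts <- c(parts, "filter.differential=1")
  if (isTRUE(fs$selected_only)) parts <- c(parts, "filter.selected=1")
  if (length(state$selections))
    parts <- c(parts, paste0("sel=", paste(state$selections, collapse = ",")))
  if (!is.null(state$list_mode))
    parts <- c(parts, paste0("list=", state$list_mode$name, ":", state$list_mode$mode))
  paste(parts, collapse = "&")
}

#' Decode a view-state parameter string
#'
#' Inverse of [encode_view_state()]. Unknown keys are an error naming
#' every offending key; a string without `genomes` is an error.
#'
#' @param text Encoded state.
#' @return A `view_state` object.
#' @export
decode_view_state <- function(text) {
  parts <- strsplit(text, "&", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  kv <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) stop("view-state parse error: token without '=': '", p, "'")
    kv[[substr(p, 1, eq - 1)]] <- substr(p, eq + 1, nchar(p))
  }
  if (length(kv) == 0L)
    stop("view-state parse error: 'genomes' is required")
  known <- names(kv) %in% c("genomes", "mode", "ref", "sel", "list",
                            "filter.biotypes", "filter.minlen", "filter.maxlen",
                            "filter.differential", "filter.selected") |
           startsWith(names(kv), "seg.")
  if (any(!known))
    stop("view-state parse error: unknown key(s): ",
         paste(names(kv)[!known], collapse = ", "))
  if (is.null(kv$genomes))
    stop("view-state parse error: 'genomes' is required")
  genomes <- strsplit(kv$genomes, ",", fixed = TRUE)[[1]]
  segments <- list()
  for (k in names(kv)[startsWith(names(kv), "seg.")]) {
    g <- substr(k, 5, nchar(k))
    if (!g %in% genomes)
      stop("view-state parse error: segment for undisplayed genome '", g, "'")
    toks <- strsplit(kv[[k]], ",", fixed = TRUE)[[1]]
    segments[[g]] <- lapply(toks, decode_segment, genome = g)
  }
  missing <- setdiff(genomes, names(segments))
  if (length(missing))
    stop("view-state parse error: no segments for genome(s): ",
         paste(missing, collapse = ", "))
  filters <- filter_spec(
    biotypes = if (!is.null(kv$`filter.biotypes`))
      strsplit(kv$`filter.biotypes`, ",", fixed = TRUE)[[1]] else NULL,
    min_length = if (!is.null(kv$`filter.minlen`)) as.numeric(kv$`filter.minlen`) else NULL,
    max_length = if (!is.null(kv$`filter.maxlen`)) as.numeric(kv$`filter.maxlen`) else NULL,
    differential = identical(kv$`filter.differential`, "1"),
    selected_only = identical(kv$`filter.selected`, "1")
  )
  list_mode <- NULL
  if (!is.null(kv$list)) {
    colon <- regexpr(":[^:]*$", kv$list)
    if (colon < 0) stop("view-state parse error: malformed list token")
    list_mode <- list(name = substr(kv$list, 1, colon - 1),
                      mode = substr(kv$list, colon + 1, nchar(kv$list)))
  }
  view_state(
    genomes, segments,
    mode = kv$mode %||% "free",
    reference = kv$ref %||% NA_character_,
    filters = filters,
    selections = if (!is.null(kv$sel)) strsplit(kv$sel, ",", fixed = TRUE)[[1]] else character(),
    list_mode = list_mode
  )
}
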