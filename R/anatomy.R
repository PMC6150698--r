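#' @name anatomy
#' @title Cell-type nomenclature and anatomical overlap
#'
#' @description
#' Central-complex cell types are named by the regions they innervate, with a
#' polarity suffix per arbor: `.s` for spiny (postsynaptic-looking) and `.b`
#' for bouton (presynaptic-looking) processes. `"PBG2-9.s-FBl3.b-NO2D.b"`
#' reads: spines in protocerebral-bridge glomeruli 2-9, boutons in fan-shaped
#' body layer 3 and in the dorsal second nodulus. Overlap between a candidate
#' presynaptic and postsynaptic type is decided at the resolution of the
#' glomerulus for the PB, the layer for the FB and the individual nodulus;
#' other regions are compared as whole compartments. Pairs whose arbors do
#' not overlap form the null sample of the screen.
NULL

# region grammar ------------------------------------------------------------

KNOWN_MODIFIERS <- c("Type1", "Type2", "contra", "contra2")
SIMPLE_REGIONS <- c("SMP", "SPS", "IB", "IMP", "AMP", "BU", "WED", "CRE",
                    "LT", "GA", "EB")

# Parse one hyphen-free token (polarity suffix already stripped) into a
# region record: list(region, detail) or NULL if unrecognized.
parse_region_token <- function(tok) {
  # PB glomerulus range: PBG2-9; PB18 / PB = all glomeruli
  m <- regmatches(tok, regexec("^PBG([0-9]+)-([0-9]+)$", tok))[[1]]
  if (length(m)) {
    lo <- as.integer(m[2]); hi <- as.integer(m[3])
    if (lo > hi) return(NULL)
    return(list(region = "PB", detail = paste(lo, hi, sep = "-")))
  }
  m <- regmatches(tok, regexec("^PBG([0-9]+)$", tok))[[1]]
  if (length(m)) return(list(region = "PB", detail = paste(m[2], m[2], sep = "-")))
  if (tok %in% c("PB", "PB18")) return(list(region = "PB", detail = "1-9"))
  # FB layers: FBl3, FBl1-3; bare FB = all layers
  if (tok == "FB") return(list(region = "FB", detail = "1-9"))
  m <- regmatches(tok, regexec("^FBl([0-9]+)(-([0-9]+))?$", tok))[[1]]
  if (length(m)) {
    lo <- as.integer(m[2]); hi <- if (nzchar(m[4])) as.integer(m[4]) else lo
    if (lo > hi) return(NULL)
    return(list(region = "FB", detail = paste(lo, hi, sep = "-")))
  }
  # EB subregions: EBw (wedge), EBt (tile)
  m <- regmatches(tok, regexec("^EB([wt])$", tok))[[1]]
  if (length(m)) return(list(region = "EB", detail = m[2]))
  # Noduli: NO<number><subcompartment letters><laterality i/c>
  m <- regmatches(tok, regexec("^NO([0-9])([ADMPV]*)([ic]?)$", tok))[[1]]
  if (length(m)) return(list(region = "NO", detail = paste0(m[2], m[3])))
  # LAL zones: LAL, LAL1..LAL3
  m <- regmatches(tok, regexec("^LAL([1-3]?)$", tok))[[1]]
  if (length(m)) return(list(region = "LAL", detail = m[2]))
  # Gall variants: GA, GAi, DV_GA, D_GAsurround ...
  if (grepl("^(DV?_)?GA", tok)) return(list(region = "GA", detail = ""))
  norm <- toupper(tok)
  if (norm == "BULB") norm <- "BU"
  if (norm == "WEDGE") norm <- "WED"
  if (norm %in% SIMPLE_REGIONS) return(list(region = norm, detail = ""))
  NULL
}

# Split a type description into tokens: hyphens separate tokens except when
# they join two digits (glomerulus / layer ranges are kept intact).
tokenize_type_name <- function(name) {
  chars <- strsplit(name, "")[[1]]
  cuts <- which(chars == "-")
  keep <- cuts[cuts > 1 & cuts < length(chars) &
               !(grepl("[0-9]", chars[cuts - 1]) & grepl("[0-9]", chars[cuts + 1]))]
  starts <- c(1L, keep + 1L)
  ends <- c(keep - 1L, length(chars))
  vapply(seq_along(starts),
         function(i) paste(chars[starts[i]:ends[i]], collapse = ""), character(1))
}

#' Parse a cell-type description into its arbor annotation
#'
#' Splits the long-name grammar (hyphen-separated region tokens, `.s`/`.b`
#' polarity suffixes, numeric ranges for PB glomeruli and FB layers) into one
#' row per arbor. Tokens without a polarity suffix inherit the nearest
#' following suffix; if none follows, the arbor is recorded with both
#' polarities. Known trailing modifiers (`.Type1`, `.contra`, ...) are kept
#' as annotations. Names listed in the packaged catalog with a curated
#' override (irregular historic names) are parsed from their override string.
#'
#' @param name type description string.
#' @param catalog optional catalog data.frame (see [celltype_catalog()]) whose
#'   curated overrides take precedence; pass `NULL` to force pure grammar
#'   parsing.
#' @return object of class `cx_arbors`: data.frame with columns `region`,
#'   `detail`, `polarity` (`"s"`, `"b"` or `"both"`), `modifier`; the type
#'   name is kept as attribute `type_name`.
#' @examples
#' parse_type_name("PBG2-9.s-FBl3.b-NO2D.b")
#' @export
parse_type_name <- function(name, catalog = celltype_catalog()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(trimws(name))) stop("empty cell-type name")
  if (!is.null(catalog)) {
    hit <- match(name, catalog$description)
    if (!is.na(hit) && nzchar(catalog$curated_arbors[hit]))
      return(structure(parse_type_name(catalog$curated_arbors[hit], catalog = NULL),
                       type_name = name))
  }
  toks <- tokenize_type_name(name)
  rows <- vector("list", length(toks))
  raw <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    parts <- strsplit(toks[i], ".", fixed = TRUE)[[1]]
    body <- parts[1]
    rest <- parts[-1]
    modifier <- paste(rest[rest %in% KNOWN_MODIFIERS], collapse = ",")
    pol <- rest[rest %in% c("s", "b")]
    extra <- rest[!rest %in% c("s", "b", KNOWN_MODIFIERS)]
    if (length(extra))
      stop(sprintf("unparseable token '%s' in '%s' (unknown suffix '%s')",
                   toks[i], name, extra[1]))
    reg <- parse_region_token(body)
    if (is.null(reg))
      stop(sprintf("unparseable token '%s' in '%s' (unknown region '%s')",
                   toks[i], name, body))
    raw[[i]] <- list(region = reg$region, detail = reg$detail,
                     pol = unique(pol), modifier = modifier)
  }
  # polarity inheritance: empty polarity takes the nearest following token's
  pols <- lapply(raw, `[[`, "pol")
  for (i in seq_along(pols)) {
    if (length(pols[[i]]) == 0) {
      nxt <- Find(function(j) length(pols[[j]]) > 0, seq_along(pols)[-seq_len(i)])
      pols[[i]] <- if (!is.null(nxt)) pols[[nxt]] else c("s", "b")
    }
  }
  for (i in seq_along(raw)) {
    p <- if (setequal(pols[[i]], c("s", "b"))) "both" else pols[[i]]
    rows[[i]] <- data.frame(region = raw[[i]]$region, detail = raw[[i]]$detail,
                            polarity = p, modifier = raw[[i]]$modifier)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("cx_arbors", "data.frame"), type_name = name)
}

#' Format an arbor annotation back into the name grammar
#'
#' Produces a canonical description string that [parse_type_name()] parses
#' back to the same region/polarity content ("both" arbors are emitted as an
#' `.s` and a `.b` token).
#'
#' @param arbors a `cx_arbors` object.
#' @return character scalar.
#' @export
format_arbors <- function(arbors) {
  stopifnot(inherits(arbors, "cx_arbors"))
  tok1 <- function(region, detail, pol, modifier) {
    body <- switch(region,
      PB = paste0("PBG", detail),
      FB = {
        r <- strsplit(detail, "-")[[1]]
        if (r[1] == r[2]) paste0("FBl", r[1]) else paste0("FBl", detail)
      },
      EB = paste0("EB", detail),
      NO = paste0("NO", detail),
      LAL = paste0("LAL", detail),
      GA = "GA",
      region)
    mod <- if (nzchar(modifier)) paste0(".", gsub(",", ".", modifier)) else ""
    paste0(body, ".", pol, mod)
  }
  toks <- unlist(lapply(seq_len(nrow(arbors)), function(i) {
    pols <- if (arbors$polarity[i] == "both") c("s", "b") else arbors$polarity[i]
    vapply(pols, function(p) tok1(arbors$region[i], arbors$detail[i], p,
                                  arbors$modifier[i]), character(1))
  }))
  paste(toks, collapse = "-")
}

# numeric range "lo-hi" -> integer set
range_set <- function(detail) {
  r <- as.integer(strsplit(detail, "-")[[1]])
  seq(r[1], r[2])
}

# Do two arbors in the same region co-localize, at that region's resolution?
details_intersect <- function(region, d1, d2) {
  switch(region,
    PB = , FB = length(intersect(range_set(d1), range_set(d2))) > 0,
    NO = {
      n1 <- substr(d1, 1, 1); n2 <- substr(d2, 1, 1)
      s1 <- substring(d1, 2); s2 <- substring(d2, 2)
      n1 == n2 && (!nzchar(s1) || !nzchar(s2) ||
                   length(intersect(strsplit(s1, "")[[1]], strsplit(s2, "")[[1]])) > 0)
    },
    LAL = !nzchar(d1) || !nzchar(d2) || d1 == d2,
    TRUE)  # EB, GA and simple regions: whole-compartment resolution
}

shared_token <- function(region, d1, d2) {
  switch(region,
    PB = paste0("PBG", paste(range(intersect(range_set(d1), range_set(d2))),
                             collapse = "-")),
    FB = paste0("FBl", paste(range(intersect(range_set(d1), range_set(d2))),
                             collapse = "-")),
    NO = paste0("NO", if (nzchar(substring(d1, 2))) d1 else d2),
    LAL = paste0("LAL", if (nzchar(d1)) d1 else d2),
    region)
}

#' Decide anatomical overlap between a candidate pre- and postsynaptic type
#'
#' A pair overlaps when some region carrying boutons (presynaptic-looking
#' processes) of the `pre` type intersects a region carrying spines of the
#' `post` type: PB at glomerulus resolution, FB at layer resolution, NO at
#' the individual nodulus, LAL at zone resolution when zones are annotated
#' (a bare `LAL` matches any zone), all other regions as whole compartments.
#' The predicate is directional: `overlap_label(a, b)` and
#' `overlap_label(b, a)` can differ.
#'
#' @param pre,post `cx_arbors` objects (or names, parsed on the fly).
#' @return list with `pre_type`, `post_type`, `overlapping` (logical) and
#'   `shared_regions` (character).
#' @export
overlap_label <- function(pre, post) {
  if (is.character(pre)) pre <- parse_type_name(pre)
  if (is.character(post)) post <- parse_type_name(post)
  stopifnot(inherits(pre, "cx_arbors"), inherits(post, "cx_arbors"))
  pb <- pre[pre$polarity %in% c("b", "both"), , drop = FALSE]
  ps <- post[post$polarity %in% c("s", "both"), , drop = FALSE]
  shared <- character(0)
  for (i in seq_len(nrow(pb))) for (j in seq_len(nrow(ps))) {
    if (pb$region[i] == ps$region[j] &&
        details_intersect(pb$region[i], pb$detail[i], ps$detail[j]))
      shared <- c(shared, shared_token(pb$region[i], pb$detail[i], ps$detail[j]))
  }
  shared <- unique(shared)
  list(pre_type = attr(pre, "type_name"), post_type = attr(post, "type_name"),
       overlapping = length(shared) > 0, shared_regions = shared)
}

#' The packaged cell-type catalog
#'
#' Short names and long descriptions of the driver lines screened, with
#' curated arbor overrides for the irregular historic names the general
#' grammar does not cover (ring neurons, the all-glomeruli PB interneuron,
#' and a few mixed-suffix names). Curated overrides are best-effort synthetic
#' annotations in the canonical grammar; users can supply their own catalog
#' CSV with the same columns.
#'
#' @param path CSV path; defaults to the catalog shipped with the package.
#' @return data.frame with columns `type_name`, `description`,
#'   `curated_arbors`.
#' @export
celltype_catalog <- function(path = system.file("extdata", "celltype_catalog.csv",
                                                package = "cxscreen")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Pairwise overlap matrix for a set of cell types
#'
#' @param types character vector of type descriptions.
#' @param catalog catalog for curated overrides.
#' @return logical matrix, rows = presynaptic candidate, columns =
#'   postsynaptic candidate.
#' @export
overlap_matrix <- function(types, catalog = celltype_catalog()) {
  ann <- lapply(types, parse_type_name, catalog = catalog)
  m <- matrix(FALSE, length(types), length(types),
              dimnames = list(pre = types, post = types))
  for (i in seq_along(types)) for (j in seq_along(types))
    m[i, j] <- overlap_label(ann[[i]], ann[[j]])$overlapping
  m
}
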