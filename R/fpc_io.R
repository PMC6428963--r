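#' Write an assembly as an FPC-style project file
#'
#' Emits a plain-text project in an FPC-V9-style dialect.  The layout,
#' line by line:
#'
#' * header: `// FPC project "<name>"` then
#'   `// dialect: wgpmap fpc text v1; coordinates in CB units`.
#' * one stanza per clone, blank-line separated:
#'   * `BAC : "<clone_id>"`
#'   * `Map "<contig_id>" Ends Left <int> Right <int>` -- the clone's
#'     CB span; singletons map to contig `"ctg0"` with span
#'     `[1, n_bands]`.
#'   * `Bands <n>` -- the clone's tag (pseudo-band) count.
#'   * for buried clones only: `Buried_into "<parent>" <marker>` with
#'     marker `=` (identical tag set) or `~` (nearly identical).
#' * one stanza per contig:
#'   * `Ctg : "<contig_id>"`
#'   * `Size <n clones incl buried>`
#'   * `Length <CB units>`
#'
#' Tokens are whitespace-separated (any mix of spaces/tabs); ids are
#' double-quoted.  [read_fpc()] inverts the writer on its own output.
#'
#' @param assembly a `wgp_assembly` with CB maps.
#' @param path output file path.
#' @param name project name for the header.
#' @return the path, invisibly.
#' @export
write_fpc <- function(assembly, path, name = "wgpmap") {
  stopifnot(inherits(assembly, "wgp_assembly"))
  for (ct in assembly$contigs)
    if (is.null(ct$cb)) stopf("contig %s has no CB map", ct$contig_id)
  fps <- assembly$fingerprints          # may be NULL (superbac-level input)
  bur <- assembly$burials
  kids <- split(bur, bur$parent_clone)

  lines <- c(sprintf("// FPC project \"%s\"", name),
             "// dialect: wgpmap fpc text v1; coordinates in CB units")

  clone_stanza <- function(id, ctg, left, right, nbands,
                           parent = NA, marker = NA) {
    s <- c(sprintf("BAC : \"%s\"", id),
           sprintf("Map \"%s\" Ends Left %d Right %d", ctg,
                   as.integer(left), as.integer(right)),
           sprintf("Bands %d", as.integer(nbands)))
    if (!is.na(parent))
      s <- c(s, sprintf("Buried_into \"%s\" %s", parent, marker))
    c("", s)
  }

  # span of a buried child inside its parent's CB map
  child_span <- function(child, cbm) {
    tags <- if (!is.null(fps) && !is.null(fps[[child]])) fps[[child]] else NULL
    if (is.null(tags) || !all(tags %in% names(cbm))) return(NULL)
    c(min(cbm[tags]), max(cbm[tags]), length(tags))
  }

  for (ct in assembly$contigs) {
    for (mreg in ct$members) {
      i <- match(mreg, ct$spans$clone_id)
      lines <- c(lines, clone_stanza(mreg, ct$contig_id,
                                     ct$spans$left[i], ct$spans$right[i],
                                     ct$spans$n_tags[i]))
      kb <- kids[[mreg]]
      if (!is.null(kb)) for (k in seq_len(nrow(kb))) {
        ch <- kb$child_clone[k]
        sp <- child_span(ch, ct$cb)
        if (is.null(sp))
          sp <- c(ct$spans$left[i], ct$spans$right[i], ct$spans$n_tags[i])
        lines <- c(lines, clone_stanza(ch, ct$contig_id, sp[1], sp[2], sp[3],
                                       parent = mreg, marker = kb$marker[k]))
      }
    }
  }
  for (s in assembly$singletons) {
    nb <- length(assembly$superbacs[[s]])
    lines <- c(lines, clone_stanza(s, "ctg0", 1L, nb, nb))
    kb <- kids[[s]]
    if (!is.null(kb)) {
      cbm <- setNames(seq_len(nb), sort(assembly$superbacs[[s]]))
      for (k in seq_len(nrow(kb))) {
        ch <- kb$child_clone[k]
        sp <- child_span(ch, cbm)
        if (is.null(sp)) sp <- c(1L, nb, nb)
        lines <- c(lines, clone_stanza(ch, "ctg0", sp[1], sp[2], sp[3],
                                       parent = s, marker = kb$marker[k]))
      }
    }
  }
  n_buried_under <- table(bur$parent_clone)
  for (ct in assembly$contigs) {
    size <- length(ct$members) +
      sum(n_buried_under[ct$members], na.rm = TRUE)
    lines <- c(lines, "",
               sprintf("Ctg : \"%s\"", ct$contig_id),
               sprintf("Size %d", as.integer(size)),
               sprintf("Length %d", as.integer(ct$length_cb)))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# one whitespace-normalized, quote-aware token split
fpc_tokens <- function(line) {
  m <- gregexpr('"[^"]*"|[^ \t]+', line)[[1L]]
  toks <- regmatches(line, list(m))[[1L]]
  gsub('^"|"$', "", toks)
}

#' Read an FPC-style project file
#'
#' Inverse of [write_fpc()] on its own output (dialect documented
#' there).  Returns an assembly *skeleton*: membership, spans, band
#' counts and burial markers, without tag-level CB maps.
#'
#' @param path file written by [write_fpc()].
#' @return object of class `wgp_fpc_project`: list with `name`,
#'   `clones` (data.frame `clone_id`, `contig_id`, `left`, `right`,
#'   `n_bands`, `buried_into`, `marker`) and `contigs` (data.frame
#'   `contig_id`, `size`, `length_cb`).
#' @export
read_fpc <- function(path) {
  raw <- readLines(path)
  bad <- function(i, why) stopf("malformed FPC stanza at line %d: %s", i, why)
  name <- NA_character_
  if (length(raw) >= 1L) {
    t0 <- fpc_tokens(raw[1L])
    if (length(t0) >= 4L && t0[1L] == "//" && t0[2L] == "FPC") name <- t0[4L]
  }
  clones <- list(); contigs <- list()
  i <- 1L; n <- length(raw)
  is_blank <- function(s) grepl("^[ \t]*$", s)
  while (i <= n) {
    line <- raw[i]
    if (is_blank(line) || grepl("^[ \t]*//", line)) { i <- i + 1L; next }
    toks <- fpc_tokens(line)
    if (toks[1L] == "BAC") {
      if (length(toks) < 3L || toks[2L] != ":") bad(i, "expected BAC : \"id\"")
      id <- toks[3L]
      if (i + 2L > n) bad(i, "truncated clone stanza")
      mt <- fpc_tokens(raw[i + 1L])
      if (length(mt) < 7L || mt[1L] != "Map" || mt[3L] != "Ends" ||
          mt[4L] != "Left" || mt[6L] != "Right")
        bad(i + 1L, "expected Map \"ctg\" Ends Left <l> Right <r>")
      bt <- fpc_tokens(raw[i + 2L])
      if (length(bt) < 2L || bt[1L] != "Bands")
        bad(i + 2L, "expected Bands <n>")
      buried_into <- NA_character_; marker <- NA_character_
      used <- 3L
      if (i + 3L <= n && !is_blank(raw[i + 3L])) {
        ut <- fpc_tokens(raw[i + 3L])
        if (ut[1L] == "Buried_into") {
          if (length(ut) < 3L || !ut[3L] %in% c("=", "~"))
            bad(i + 3L, "expected Buried_into \"parent\" = or ~")
          buried_into <- ut[2L]; marker <- ut[3L]
          used <- 4L
        }
      }
      clones[[length(clones) + 1L]] <- data.frame(
        clone_id = id, contig_id = mt[2L],
        left = as.integer(mt[5L]), right = as.integer(mt[7L]),
        n_bands = as.integer(bt[2L]),
        buried_into = buried_into, marker = marker)
      i <- i + used
    } else if (toks[1L] == "Ctg") {
      if (length(toks) < 3L || toks[2L] != ":") bad(i, "expected Ctg : \"id\"")
      if (i + 2L > n) bad(i, "truncated contig stanza")
      st <- fpc_tokens(raw[i + 1L])
      lt <- fpc_tokens(raw[i + 2L])
      if (length(st) < 2L || st[1L] != "Size") bad(i + 1L, "expected Size <n>")
      if (length(lt) < 2L || lt[1L] != "Length")
        bad(i + 2L, "expected Length <n>")
      contigs[[length(contigs) + 1L]] <- data.frame(
        contig_id = toks[3L], size = as.integer(st[2L]),
        length_cb = as.integer(lt[2L]))
      i <- i + 3L
    } else bad(i, sprintf("unexpected token `%s`", toks[1L]))
  }
  empty_clones <- data.frame(clone_id = character(), contig_id = character(),
                             left = integer(), right = integer(),
                             n_bands = integer(), buried_into = character(),
                             marker = character())
  empty_ctgs <- data.frame(contig_id = character(), size = integer(),
                           length_cb = integer())
  structure(list(name = name,
                 clones = if (length(clones)) do.call(rbind, clones)
                 else empty_clones,
                 contigs = if (length(contigs)) do.call(rbind, contigs)
                 else empty_ctgs),
            class = "wgp_fpc_project")
}
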