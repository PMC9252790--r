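#' Read motif models from files
#'
#' Accepts any mix of JASPAR-style PFM text files (4-row count matrices under
#' a `>` header, optionally several per file), TFFM XML files (the strict
#' states/transitions/emissions dialect documented in
#' [read_tffm_xml()]) and the package's JSON model format
#' ([read_model_json()]). The format of each file is auto-detected from its
#' first non-blank character (`>` PFM, `<` XML, `{`/`[` JSON). PFMs are
#' returned as PWMs via [pcm_to_pwm()].
#'
#' @param paths Character vector of files and/or directories (directories are
#'   expanded non-recursively).
#' @param bg Background distribution for PCM-to-PWM conversion.
#' @param pseudocount Passed to [pcm_to_pwm()].
#' @return A list of motif models. Duplicated `model_id`s raise an error.
#' @export
read_models <- function(paths, bg = dna_background(), pseudocount = NULL) {
  files <- unlist(lapply(paths, function(p) {
    if (dir.exists(p)) list.files(p, full.names = TRUE) else p
  }))
  if (length(files) == 0L) stop("no model files found", call. = FALSE)
  models <- list()
  for (f in files) {
    first <- substr(trimws(readChar(f, min(file.size(f), 200L))), 1L, 1L)
    new <- switch(first,
      ">" = lapply(read_jaspar_pfm(f), pcm_to_pwm, bg = bg,
                   pseudocount = pseudocount),
      "<" = list(read_tffm_xml(f)),
      "{" = list(read_model_json(f)),
      "[" = read_model_json(f),
      stop(sprintf("cannot detect model format of %s", f), call. = FALSE)
    )
    models <- c(models, new)
  }
  ids <- vapply(models, `[[`, character(1), "model_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate model_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  models
}

#' Read JASPAR-style PFM text
#'
#' Parses count matrices in the JASPAR text format: a header line
#' `>MODEL_ID TF_NAME` followed by four rows of counts, either labelled
#' (`A [ 3 5 ... ]`) or plain whitespace-separated numbers in A, C, G, T
#' order. Several records per file are allowed.
#'
#' @param path Path to the PFM file.
#' @param source Source label attached to the models.
#' @return A list of [pcm()] objects.
#' @export
read_jaspar_pfm <- function(path, source = "JASPAR") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no PFM header line ('>') found", call. = FALSE)
  out <- vector("list", length(headers))
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    hdr <- sub("^>\\s*", "", lines[headers[i]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1L]]
    model_id <- toks[1L]
    tf_name <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else toks[1L]
    body <- lines[(headers[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4L) {
      stop(sprintf("PFM record %s must have exactly 4 count rows", model_id),
           call. = FALSE)
    }
    rows <- lapply(body, function(l) {
      lab <- regmatches(l, regexec("^\\s*([ACGTacgt])[\\s\\[]", l))[[1L]]
      nums <- as.numeric(strsplit(trimws(gsub("[^0-9.eE+-]", " ", l)), "\\s+")[[1L]])
      list(label = if (length(lab)) toupper(lab[2L]) else NA_character_,
           counts = nums[!is.na(nums)])
    })
    labels <- vapply(rows, `[[`, character(1), "label")
    counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
    if (!anyNA(labels)) {
      if (!setequal(labels, DNA_BASES)) {
        stop(sprintf("PFM record %s has invalid row labels", model_id),
             call. = FALSE)
      }
      counts <- counts[match(DNA_BASES, labels), , drop = FALSE]
    }
    out[[i]] <- pcm(counts, tf_name = tf_name, model_id = model_id,
                    source = source)
  }
  out
}

number_vec <- function(x) as.numeric(strsplit(trimws(x), "\\s+")[[1L]])

#' Read a TFFM from XML
#'
#' Reads the strict XML dialect used by this package for both TFFM flavours.
#' The root element is `<tffm kind="first_order|detailed" tf_name=...
#' model_id=... source=...>` with exactly two children:
#'
#' * `<states>`: for first-order models, one `<state kind="background">`
#'   carrying an `<emission>` (4 numbers, marginal first-base distribution)
#'   and four `<conditional previous="A|C|G|T">` rows, plus one
#'   `<state kind="motif" position="i">` per motif position with four
#'   `<conditional>` rows. For detailed models, `<state kind="background"
#'   base="A" initial="0.295">` and `<state kind="motif" position="i"
#'   base="b">` elements (4 per position), without emissions.
#' * `<transitions>`: `<transition from="ID" to="ID" prob="p"/>` elements.
#'   First-order models need the background self-transition and motif-entry
#'   probabilities; the deterministic motif-chain transitions may be given
#'   and are validated. Detailed models list every non-zero transition.
#'
#' Any unrecognised element or attribute combination is a hard error rather
#' than a silent default.
#'
#' @param path Path to the XML file.
#' @return A `"tffm_first"` or `"tffm_detailed"` model.
#' @export
read_tffm_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "tffm") {
    stop("root element must be <tffm>", call. = FALSE)
  }
  kind <- xml2::xml_attr(doc, "kind")
  meta <- list(tf_name = xml2::xml_attr(doc, "tf_name"),
               model_id = xml2::xml_attr(doc, "model_id"),
               source = xml2::xml_attr(doc, "source"))
  if (anyNA(unlist(meta))) {
    stop("<tffm> needs kind, tf_name, model_id and source attributes",
         call. = FALSE)
  }
  kids <- xml2::xml_name(xml2::xml_children(doc))
  if (!setequal(kids, c("states", "transitions")) || length(kids) != 2L) {
    stop("<tffm> must contain exactly <states> and <transitions>", call. = FALSE)
  }
  st_kids <- xml2::xml_name(xml2::xml_children(xml2::xml_find_first(doc, "./states")))
  tr_kids <- xml2::xml_name(xml2::xml_children(xml2::xml_find_first(doc, "./transitions")))
  if (!all(st_kids == "state") || !all(tr_kids == "transition")) {
    stop("unrecognised element inside <states> or <transitions>", call. = FALSE)
  }
  states <- xml2::xml_find_all(doc, "./states/state")
  for (s in seq_along(states)) {
    ck <- xml2::xml_name(xml2::xml_children(states[[s]]))
    if (!all(ck %in% c("emission", "conditional"))) {
      stop("unrecognised element inside <state>", call. = FALSE)
    }
  }
  trans <- xml2::xml_find_all(doc, "./transitions/transition")
  if (identical(kind, "first_order")) {
    parse_tffm_xml_first(states, trans, meta)
  } else if (identical(kind, "detailed")) {
    parse_tffm_xml_detailed(states, trans, meta)
  } else {
    stop(sprintf("unknown TFFM kind: %s", kind), call. = FALSE)
  }
}

conditional_matrix <- function(state_node, id) {
  conds <- xml2::xml_find_all(state_node, "./conditional")
  if (length(conds) != 4L) {
    stop(sprintf("state %s needs exactly 4 <conditional> rows", id),
         call. = FALSE)
  }
  prev <- xml2::xml_attr(conds, "previous")
  if (!setequal(prev, DNA_BASES)) {
    stop(sprintf("state %s conditional rows must cover previous A,C,G,T", id),
         call. = FALSE)
  }
  m <- do.call(rbind, lapply(xml2::xml_text(conds), number_vec))
  m <- m[match(DNA_BASES, prev), , drop = FALSE]
  dimnames(m) <- list(DNA_BASES, DNA_BASES)
  m
}

parse_tffm_xml_first <- function(states, trans, meta) {
  kind <- xml2::xml_attr(states, "kind")
  ids <- xml2::xml_attr(states, "id")
  if (anyNA(ids) || anyDuplicated(ids)) {
    stop("every <state> needs a unique id", call. = FALSE)
  }
  bg_i <- which(kind == "background")
  mot_i <- which(kind == "motif")
  if (length(bg_i) != 1L || length(mot_i) < 1L ||
      length(bg_i) + length(mot_i) != length(states)) {
    stop("first-order TFFM needs one background and >= 1 motif states",
         call. = FALSE)
  }
  pos <- as.integer(xml2::xml_attr(states[mot_i], "position"))
  if (anyNA(pos) || !identical(sort(pos), seq_along(mot_i))) {
    stop("motif states must carry positions 1..L", call. = FALSE)
  }
  mot_i <- mot_i[order(pos)]
  em <- xml2::xml_find_all(states[bg_i], "./emission")
  if (length(em) != 1L) {
    stop("background state needs exactly one <emission>", call. = FALSE)
  }
  bg_emission <- setNames(number_vec(xml2::xml_text(em)), DNA_BASES)
  bg_conditional <- conditional_matrix(states[[bg_i]], ids[bg_i])
  motif_conditional <- lapply(seq_along(mot_i), function(j) {
    conditional_matrix(states[[mot_i[j]]], ids[mot_i[j]])
  })
  from <- xml2::xml_attr(trans, "from")
  to <- xml2::xml_attr(trans, "to")
  prob <- as.numeric(xml2::xml_attr(trans, "prob"))
  if (anyNA(from) || anyNA(to) || anyNA(prob)) {
    stop("every <transition> needs from, to and prob", call. = FALSE)
  }
  bg_id <- ids[bg_i]
  m_ids <- ids[mot_i]
  self_transition <- motif_entry <- NA_real_
  L <- length(m_ids)
  for (k in seq_along(from)) {
    if (from[k] == bg_id && to[k] == bg_id) self_transition <- prob[k]
    else if (from[k] == bg_id && to[k] == m_ids[1L]) motif_entry <- prob[k]
    else if (from[k] %in% m_ids) {
      i <- match(from[k], m_ids)
      ok_to <- if (i < L) m_ids[i + 1L] else bg_id
      if (to[k] != ok_to || abs(prob[k] - 1) > 1e-9) {
        stop(sprintf("invalid motif-chain transition %s -> %s", from[k], to[k]),
             call. = FALSE)
      }
    } else {
      stop(sprintf("unrecognised transition %s -> %s", from[k], to[k]),
           call. = FALSE)
    }
  }
  if (is.na(self_transition) || is.na(motif_entry)) {
    stop("first-order TFFM needs background self-transition and motif entry",
         call. = FALSE)
  }
  tffm_first_order(motif_conditional, bg_emission, bg_conditional,
                   self_transition, motif_entry,
                   tf_name = meta$tf_name, model_id = meta$model_id,
                   source = meta$source)
}

parse_tffm_xml_detailed <- function(states, trans, meta) {
  kind <- xml2::xml_attr(states, "kind")
  ids <- xml2::xml_attr(states, "id")
  base <- xml2::xml_attr(states, "base")
  if (anyNA(ids) || anyDuplicated(ids) || anyNA(base) ||
      !all(base %in% DNA_BASES)) {
    stop("every detailed state needs a unique id and a base A/C/G/T",
         call. = FALSE)
  }
  bg_i <- which(kind == "background")
  mot_i <- which(kind == "motif")
  if (length(bg_i) != 4L || length(mot_i) %% 4L != 0L || length(mot_i) == 0L ||
      length(bg_i) + length(mot_i) != length(states)) {
    stop("detailed TFFM needs 4 background and 4L motif states", call. = FALSE)
  }
  L <- length(mot_i) %/% 4L
  pos <- as.integer(xml2::xml_attr(states[mot_i], "position"))
  if (anyNA(pos) || !all(sort(unique(pos)) == seq_len(L))) {
    stop("motif states must carry positions 1..L", call. = FALSE)
  }
  # canonical state order: background A..T, then per position base A..T
  order_key <- function(i) {
    if (kind[i] == "background") match(base[i], DNA_BASES)
    else 4L + 4L * (as.integer(xml2::xml_attr(states[i], "position")) - 1L) +
      match(base[i], DNA_BASES)
  }
  keys <- vapply(seq_along(states), order_key, integer(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (position, base) detailed state", call. = FALSE)
  }
  n <- length(states)
  id_to_index <- setNames(keys, ids)  # id -> canonical state index
  initial <- rep(0, 4)
  init_attr <- as.numeric(xml2::xml_attr(states[bg_i], "initial"))
  if (anyNA(init_attr)) {
    stop("background states need initial probabilities", call. = FALSE)
  }
  initial[vapply(bg_i, order_key, integer(1))] <- init_attr
  from <- xml2::xml_attr(trans, "from")
  to <- xml2::xml_attr(trans, "to")
  prob <- as.numeric(xml2::xml_attr(trans, "prob"))
  if (anyNA(from) || anyNA(to) || anyNA(prob) ||
      !all(from %in% ids) || !all(to %in% ids)) {
    stop("every <transition> needs known from/to ids and a prob", call. = FALSE)
  }
  A <- matrix(0, n, n)
  A[cbind(id_to_index[from], id_to_index[to])] <- prob
  tffm_detailed(A, initial, tf_name = meta$tf_name, model_id = meta$model_id,
                source = meta$source)
}

#' Write a TFFM to the package XML dialect
#'
#' Inverse of [read_tffm_xml()].
#'
#' @param x A `"tffm_first"` or `"tffm_detailed"` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tffm_xml <- function(x, path) {
  stopifnot(is_tffm(x))
  num <- function(v) paste(format(v, digits = 17, trim = TRUE), collapse = " ")
  lines <- character(0)
  if (inherits(x, "tffm_first")) {
    lines <- c(lines, sprintf(
      '<tffm kind="first_order" tf_name="%s" model_id="%s" source="%s">',
      x$tf_name, x$model_id, x$source), "  <states>",
      '    <state id="B" kind="background">',
      sprintf("      <emission>%s</emission>", num(x$bg_emission)),
      vapply(1:4, function(p) sprintf(
        '      <conditional previous="%s">%s</conditional>',
        DNA_BASES[p], num(x$bg_conditional[p, ])), character(1)),
      "    </state>")
    for (i in seq_len(x$L)) {
      lines <- c(lines,
        sprintf('    <state id="M%d" kind="motif" position="%d">', i, i),
        vapply(1:4, function(p) sprintf(
          '      <conditional previous="%s">%s</conditional>',
          DNA_BASES[p], num(x$motif_conditional[[i]][p, ])), character(1)),
        "    </state>")
    }
    chain <- c(
      sprintf('    <transition from="B" to="B" prob="%s"/>', num(x$self_transition)),
      sprintf('    <transition from="B" to="M1" prob="%s"/>', num(x$motif_entry)),
      if (x$L > 1) sprintf('    <transition from="M%d" to="M%d" prob="1"/>',
                           seq_len(x$L - 1), seq_len(x$L - 1) + 1L),
      sprintf('    <transition from="M%d" to="B" prob="1"/>', x$L))
    lines <- c(lines, "  </states>", "  <transitions>", chain,
               "  </transitions>", "</tffm>")
  } else {
    n <- nrow(x$transition)
    state_id <- function(i) {
      if (x$state_pos[i] == 0L) sprintf("B.%s", DNA_BASES[x$state_base[i]])
      else sprintf("M%d.%s", x$state_pos[i], DNA_BASES[x$state_base[i]])
    }
    ids <- vapply(seq_len(n), state_id, character(1))
    lines <- c(lines, sprintf(
      '<tffm kind="detailed" tf_name="%s" model_id="%s" source="%s">',
      x$tf_name, x$model_id, x$source), "  <states>",
      vapply(1:4, function(i) sprintf(
        '    <state id="%s" kind="background" base="%s" initial="%s"/>',
        ids[i], DNA_BASES[x$state_base[i]], num(x$initial[i])), character(1)),
      vapply(5:n, function(i) sprintf(
        '    <state id="%s" kind="motif" position="%d" base="%s"/>',
        ids[i], x$state_pos[i], DNA_BASES[x$state_base[i]]), character(1)),
      "  </states>", "  <transitions>")
    nz <- which(x$transition > 0, arr.ind = TRUE)
    lines <- c(lines, vapply(seq_len(nrow(nz)), function(k) sprintf(
      '    <transition from="%s" to="%s" prob="%s"/>',
      ids[nz[k, 1L]], ids[nz[k, 2L]], num(x$transition[nz[k, 1L], nz[k, 2L]])),
      character(1)),
      "  </transitions>", "</tffm>")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write motif models in the package JSON format
#'
#' A self-describing JSON object with fields `format`
#' (`"tfshift-model"`), `kind` (`"pcm"`, `"tffm_first"` or
#' `"tffm_detailed"`), the metadata `tf_name` / `model_id` / `source`, and
#' the kind-specific numeric fields: `counts` (4 x L, row order A, C, G, T)
#' for PCMs; `bg_emission`, `bg_conditional`, `motif_conditional`,
#' `self_transition`, `motif_entry` for first-order TFFMs; `transition` and
#' `initial` for detailed TFFMs. Probabilities survive a round trip to at
#' least 1e-12.
#'
#' @param x A `"pcm"`, `"tffm_first"` or `"tffm_detailed"` model.
#' @param path File path.
#' @return `read_model_json()` returns the model (PCMs stay PCMs; convert
#'   with [pcm_to_pwm()]); `write_model_json()` returns `path` invisibly.
#' @export
write_model_json <- function(x, path) {
  obj <- if (inherits(x, "pcm")) {
    list(kind = "pcm", counts = unname(x$counts))
  } else if (inherits(x, "tffm_first")) {
    list(kind = "tffm_first", bg_emission = unname(x$bg_emission),
         bg_conditional = unname(x$bg_conditional),
         motif_conditional = lapply(x$motif_conditional, unname),
         self_transition = x$self_transition, motif_entry = x$motif_entry)
  } else if (inherits(x, "tffm_detailed")) {
    list(kind = "tffm_detailed", transition = unname(x$transition),
         initial = unname(x$initial))
  } else {
    stop("unsupported model type for JSON export", call. = FALSE)
  }
  obj <- c(list(format = "tfshift-model"), obj,
           list(tf_name = x$tf_name, model_id = x$model_id, source = x$source))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(obj$format, "tfshift-model")) {
    stop("not a tfshift-model JSON file", call. = FALSE)
  }
  switch(obj$kind,
    pcm = pcm(obj$counts, obj$tf_name, obj$model_id, obj$source),
    tffm_first = {
      mc <- obj$motif_conditional
      if (is.array(mc) && length(dim(mc)) == 3L) {
        mc <- lapply(seq_len(dim(mc)[1L]), function(i) mc[i, , ])
      }
      tffm_first_order(mc, setNames(obj$bg_emission, DNA_BASES),
                       obj$bg_conditional, obj$self_transition,
                       obj$motif_entry, obj$tf_name, obj$model_id, obj$source)
    },
    tffm_detailed = tffm_detailed(obj$transition, obj$initial,
                                  obj$tf_name, obj$model_id, obj$source),
    stop(sprintf("unknown model kind in JSON: %s", obj$kind), call. = FALSE)
  )
}
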