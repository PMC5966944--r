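#' Read / write a network as plain-text reaction tables
#'
#' Tab-separated dialect, UTF-8, `#` comment lines. Reaction table columns:
#' `reaction_id  name  kind  reversible(0/1)  capacity(number or "inf")
#' stoichiometry`, with stoichiometry written as `metId:coeff` pairs joined
#' by `;` (e.g. `g6p:-1;f6p:1`). A sibling metabolite table (same path with
#' `_metabolites` inserted before the extension) carries
#' `met_id  name  role  compartment_tag  is_cofactor`. Writing canonicalises
#' stoichiometry order (sorted by metabolite id), so write-then-read is the
#' identity on the data model and write is bit-stable.
#'
#' @param path reaction-table path.
#' @param metabolite_path metabolite-table path; default derived from
#'   `path`. When reading, a missing metabolite table makes all metabolites
#'   internal non-cofactors (with a warning).
#' @return `load_reaction_table`: a validated `vf_network`;
#'   `write_reaction_table`: `path`, invisibly.
#' @export
load_reaction_table <- function(path, metabolite_path = sibling_met_path(path)) {
  if (!file.exists(path)) vf_stop("reaction table not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(!grepl("^\\s*(#|$)", lines))

  mets <- NULL
  if (!is.null(metabolite_path) && file.exists(metabolite_path)) {
    mlines <- readLines(metabolite_path, encoding = "UTF-8")
    mlines <- mlines[!grepl("^\\s*(#|$)", mlines)]
    mets <- lapply(seq_along(mlines), function(i) {
      f <- strsplit(mlines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) != 5L)
        vf_stop("%s line %d: expected 5 tab-separated fields, got %d",
                metabolite_path, i, length(f))
      metabolite(f[1], f[2], f[3], f[4], cofactor = f[5] %in% c("1", "true", "TRUE"))
    })
  }

  reactions <- vector("list", length(keep))
  seen_mets <- character(0)
  for (k in seq_along(keep)) {
    i <- keep[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6L)
      vf_stop("%s line %d: expected 6 tab-separated fields, got %d", path, i, length(f))
    cap <- if (tolower(f[5]) %in% c("inf", "na", "")) NA_real_ else suppressWarnings(as.numeric(f[5]))
    if (!tolower(f[5]) %in% c("inf", "na", "") && is.na(cap))
      vf_stop("%s line %d: malformed capacity '%s'", path, i, f[5])
    pairs <- strsplit(f[6], ";", fixed = TRUE)[[1]]
    st <- numeric(0)
    for (p in pairs) {
      kv <- strsplit(p, ":", fixed = TRUE)[[1]]
      if (length(kv) != 2L)
        vf_stop("%s line %d: malformed stoichiometry pair '%s'", path, i, p)
      coef <- suppressWarnings(as.numeric(kv[2]))
      if (is.na(coef))
        vf_stop("%s line %d: malformed coefficient '%s' for metabolite '%s'",
                path, i, kv[2], kv[1])
      st[kv[1]] <- coef
    }
    if (!is.null(mets)) {
      unknown <- setdiff(names(st), vapply(mets, `[[`, "", "id"))
      if (length(unknown))
        vf_stop("%s line %d: unknown metabolite id(s) in stoichiometry: %s",
                path, i, paste(unknown, collapse = ", "))
    }
    seen_mets <- union(seen_mets, names(st))
    reactions[[k]] <- reaction(f[1], st, reversible = f[4] == "1",
                               kind = f[3], capacity = cap, name = f[2])
  }
  if (is.null(mets)) {
    vf_warn("no metabolite table at '%s'; treating all metabolites as internal",
            metabolite_path %||% "<none>")
    mets <- lapply(sort(seen_mets), function(id) metabolite(id))
  }
  stoichiometric_network(mets, reactions,
                         provenance = sprintf("loaded from %s", basename(path)))
}

#' @rdname load_reaction_table
#' @param network a `vf_network`.
#' @export
write_reaction_table <- function(network, path,
                                 metabolite_path = sibling_met_path(path)) {
  validate_network(network)
  fmt_num <- function(x) formatC(x, format = "g", digits = 15)
  rlines <- vapply(network$reactions, function(r) {
    st <- r$stoich[order(names(r$stoich))]
    paste(r$id, r$name, r$kind, if (r$reversible) "1" else "0",
          if (is.na(r$capacity)) "inf" else fmt_num(r$capacity),
          paste(sprintf("%s:%s", names(st), fmt_num(st)), collapse = ";"),
          sep = "\t")
  }, "")
  writeLines(c("# reaction_id\tname\tkind\treversible\tcapacity\tstoichiometry",
               rlines), path, useBytes = TRUE)
  mlines <- vapply(network$metabolites, function(m) {
    paste(m$id, m$name, m$role, m$compartment, if (m$cofactor) "1" else "0",
          sep = "\t")
  }, "")
  writeLines(c("# met_id\tname\trole\tcompartment_tag\tis_cofactor", mlines),
             metabolite_path, useBytes = TRUE)
  invisible(path)
}

sibling_met_path <- function(path) {
  if (is.null(path)) return(NULL)
  sub("(\\.[^./\\\\]*)?$", "_metabolites\\1", path)
}
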