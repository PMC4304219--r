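# Plain-text interchange formats: a long-format TSV for module membership
# (module_id, role, member_id, coefficient), a companion summary TSV with
# the per-module scores, an optional GMT export, and a flat key/value config
# format. Numbers are written with 10 significant digits so round-trips are
# lossless at that precision.

summary_path_for <- function(path) {
  paste0(sub("\\.tsv$", "", path), "_summary.tsv")
}

#' Write modules to a long-format TSV (plus a summary TSV)
#'
#' The main file has columns `module_id`, `role` (`gene` or `regulator`),
#' `member_id`, `coefficient` (empty for genes). A companion summary file at
#' `<path minus .tsv>_summary.tsv` carries `module_id`, `n_genes`,
#' `n_regulators`, `cv_r2`, `r2_train`, `r2_test`, `adj_r2_test`.
#'
#' @param modules List of `Module`s (may be empty).
#' @param path Output path for the long-format file.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  lines <- c("module_id\trole\tmember_id\tcoefficient")
  sm <- c("module_id\tn_genes\tn_regulators\tcv_r2\tr2_train\tr2_test\tadj_r2_test")
  for (m in modules) {
    lines <- c(lines,
               sprintf("%s\tgene\t%s\t", m$module_id, m$genes),
               sprintf("%s\tregulator\t%s\t%s", m$module_id, m$regulators,
                       fmt_num(m$coefficients)))
    sm <- c(sm, sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s",
                        m$module_id, length(m$genes), length(m$regulators),
                        fmt_num(m$cv_r2), fmt_num(m$r2_train),
                        fmt_num(m$r2_test), fmt_num(m$adj_r2_test)))
  }
  writeLines(lines, path)
  writeLines(sm, summary_path_for(path))
  invisible(path)
}

#' Read modules from a long-format TSV
#'
#' Inverse of [write_modules()]; scores are restored from the companion
#' summary file when present. Unknown role tokens are format errors.
#'
#' @param path Path to the long-format module file.
#' @return List of `Module`s.
#' @export
read_modules <- function(path) {
  if (!file.exists(path)) camodi_stop("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  if (!identical(colnames(df), c("module_id", "role", "member_id", "coefficient")))
    camodi_stop("malformed module file: %s", path)
  bad_role <- setdiff(unique(df$role), c("gene", "regulator"))
  if (length(bad_role))
    camodi_stop("unknown role token '%s' in %s", bad_role[1], path)
  sp <- summary_path_for(path)
  summ <- NULL
  if (file.exists(sp))
    summ <- utils::read.delim(sp, header = TRUE, sep = "\t", quote = "",
                              check.names = FALSE)
  out <- lapply(unique(df$module_id), function(id) {
    rows <- df[df$module_id == id, , drop = FALSE]
    genes <- rows$member_id[rows$role == "gene"]
    reg_rows <- rows[rows$role == "regulator", , drop = FALSE]
    coefs <- suppressWarnings(as.numeric(reg_rows$coefficient))
    if (anyNA(coefs) || any(coefs == 0))
      camodi_stop("module '%s': regulator rows need non-zero numeric coefficients", id)
    names(coefs) <- reg_rows$member_id
    scores <- list(cv_r2 = NA_real_, r2_train = NA_real_,
                   r2_test = NA_real_, adj_r2_test = NA_real_)
    if (!is.null(summ) && id %in% summ$module_id) {
      srow <- summ[summ$module_id == id, , drop = FALSE][1, ]
      scores <- list(cv_r2 = srow$cv_r2, r2_train = srow$r2_train,
                     r2_test = srow$r2_test, adj_r2_test = srow$adj_r2_test)
    }
    new_module(id, genes, coefs, cv_r2 = scores$cv_r2,
               r2_train = scores$r2_train, r2_test = scores$r2_test,
               adj_r2_test = scores$adj_r2_test)
  })
  out
}

#' Export module gene sets in GMT format
#'
#' One line per module: `module_id<TAB>description<TAB>gene1<TAB>gene2...`,
#' for interoperability with gene-set tools.
#'
#' @param modules List of `Module`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(modules, path) {
  lines <- vapply(modules, function(m) {
    desc <- sprintf("regulators:%s", paste(m$regulators, collapse = ","))
    paste(c(m$module_id, desc, m$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a flat key-value configuration file
#'
#' One `key<TAB>value` pair per line; numeric values are restored as numeric.
#'
#' @param config A [camodi_config()] list.
#' @param path File path.
#' @return `write_config`: `path` invisibly; `read_config`: a validated
#'   `CamodiConfig`.
#' @export
write_config <- function(config, path) {
  keys <- names(config)
  vals <- vapply(config, function(v)
    if (is.numeric(v)) fmt_num(v) else as.character(v), character(1))
  writeLines(sprintf("%s\t%s", keys, vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) camodi_stop("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[`, character(1), 1)
  vals <- vapply(parts, `[`, character(1), 2)
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  names(out) <- keys
  do.call(camodi_config, out)
}
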