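# Activation-focus databases: data model, Sleuth/TSV I/O, seed selection.

#' Construct an experiment record
#'
#' One neuroimaging experiment (a reported group contrast): a subject
#' count, a set of activation peak coordinates in MNI millimetres, and an
#' optional set of taxonomy labels (behavioural domain / paradigm class).
#'
#' @param id unique experiment identifier.
#' @param n_subjects number of subjects (>= 1).
#' @param foci numeric n x 3 matrix of MNI-mm peak coordinates (>= 1 row).
#' @param labels character vector of taxonomy labels (may be empty).
#' @return An object of class `experiment`.
#' @export
experiment <- function(id, n_subjects, foci, labels = character(0)) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) stop("n_subjects must be >= 1")
  foci <- matrix(as.numeric(foci), ncol = 3L,
                 dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(foci) < 1L) stop(sprintf("experiment '%s' has no foci", id))
  if (any(!is.finite(foci))) stop(sprintf("experiment '%s' has non-finite foci", id))
  structure(list(id = id, n_subjects = n_subjects, foci = foci,
                 labels = unique(as.character(labels))),
            class = "experiment")
}

#' Construct a foci database
#'
#' @param experiments list of [experiment] objects with unique ids.
#' @param space_tag coordinate space tag; only `"MNI"` is supported.
#' @return An object of class `foci_db`.
#' @export
foci_db <- function(experiments, space_tag = "MNI") {
  stopifnot(is.list(experiments))
  if (!identical(space_tag, "MNI"))
    stop("unsupported space: ", space_tag)
  ids <- vapply(experiments, function(e) e$id, character(1))
  if (anyDuplicated(ids)) stop("experiment ids must be unique")
  structure(list(experiments = experiments, space_tag = space_tag),
            class = "foci_db")
}

#' @export
print.foci_db <- function(x, ...) {
  nf <- sum(vapply(x$experiments, function(e) nrow(e$foci), integer(1)))
  cat(sprintf("foci_db: %d experiments, %d foci (%s space)\n",
              length(x$experiments), nf, x$space_tag))
  invisible(x)
}

#' @export
length.foci_db <- function(x) length(x$experiments)

#' Experiment ids of a database
#' @param db a [foci_db].
#' @return Character vector of experiment ids, in database order.
#' @export
db_ids <- function(db) vapply(db$experiments, function(e) e$id, character(1))

#' Parse a Sleuth-style foci text file
#'
#' Dialect: a `// Reference=MNI` header; per-experiment blocks of the form
#' `// <name>` line(s), a `// Subjects=<n>` line, then one whitespace
#' separated `x y z` coordinate per line; blank lines separate blocks.
#' A Talairach reference tag is rejected (no coordinate conversion is
#' implemented).
#'
#' @param text character scalar (entire file contents) or vector of lines.
#' @return A [foci_db].
#' @export
parse_sleuth_text <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  lines <- sub("\r$", "", lines)
  ref <- grep("^//\\s*Reference\\s*=", lines, value = TRUE)
  if (length(ref) >= 1L) {
    space <- trimws(sub("^//\\s*Reference\\s*=", "", ref[1]))
    if (toupper(space) != "MNI") stop("unsupported space: ", space)
  }
  lines <- lines[!grepl("^//\\s*Reference\\s*=", lines)]
  # split into blocks at blank lines
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, diff(!blank) == 1) & !blank)
  grp[blank] <- 0L
  blocks <- split(lines[!blank], grp[!blank])
  exps <- list()
  for (b in blocks) {
    comments <- b[startsWith(trimws(b), "//")]
    coords <- b[!startsWith(trimws(b), "//")]
    name_lines <- comments[!grepl("Subjects\\s*=", comments)]
    name <- if (length(name_lines)) trimws(sub("^//", "", name_lines[1])) else
      sprintf("experiment_%d", length(exps) + 1L)
    subj <- grep("^//\\s*Subjects\\s*=", comments, value = TRUE)
    if (length(subj) != 1L)
      stop(sprintf("block '%s': missing Subjects line", name))
    n <- suppressWarnings(as.integer(trimws(sub("^//\\s*Subjects\\s*=", "", subj))))
    if (is.na(n)) stop(sprintf("block '%s': non-numeric Subjects", name))
    if (length(coords) == 0L)
      stop(sprintf("block '%s': no coordinates", name))
    xyz <- lapply(coords, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (length(v) != 3L || anyNA(v))
        stop(sprintf("block '%s': bad coordinate line '%s'", name, l))
      v
    })
    id <- name
    k <- 1L
    while (id %in% vapply(exps, function(e) e$id, character(1))) {
      k <- k + 1L
      id <- sprintf("%s#%d", name, k)
    }
    exps[[length(exps) + 1L]] <- experiment(id, n, do.call(rbind, xyz))
  }
  foci_db(exps)
}

#' Read a Sleuth-style foci file
#' @param path file path.
#' @return A [foci_db].
#' @export
read_sleuth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_sleuth_text(readLines(path, warn = FALSE))
}

#' Write a foci database in Sleuth dialect
#' @param db a [foci_db].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sleuth <- function(db, path) {
  stopifnot(inherits(db, "foci_db"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("// Reference=MNI", con)
  writeLines("", con)
  for (e in db$experiments) {
    writeLines(sprintf("// %s", e$id), con)
    writeLines(sprintf("// Subjects=%d", e$n_subjects), con)
    writeLines(apply(e$foci, 1, function(r) paste(format(r, trim = TRUE), collapse = "\t")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a tabular (TSV) foci database
#'
#' Columns: `id`, `n_subjects`, `x`, `y`, `z`, optional `labels`
#' (`;`-separated). One row per focus; rows sharing an id form one
#' experiment (n_subjects and labels taken from its first row).
#'
#' @param path TSV file path.
#' @return A [foci_db].
#' @export
read_foci_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "n_subjects", "x", "y", "z")
  if (!all(need %in% names(d))) stop("missing columns: ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  exps <- lapply(split(d, factor(d$id, levels = unique(d$id))), function(g) {
    labels <- if ("labels" %in% names(g) && nzchar(g$labels[1]))
      strsplit(g$labels[1], ";", fixed = TRUE)[[1]] else character(0)
    experiment(as.character(g$id[1]), g$n_subjects[1],
               cbind(g$x, g$y, g$z), trimws(labels))
  })
  foci_db(unname(exps))
}

#' Write a foci database as TSV
#' @param db a [foci_db].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_foci_tsv <- function(db, path) {
  stopifnot(inherits(db, "foci_db"))
  rows <- lapply(db$experiments, function(e) {
    data.frame(id = e$id, n_subjects = e$n_subjects,
               x = e$foci[, 1], y = e$foci[, 2], z = e$foci[, 3],
               labels = paste(e$labels, collapse = ";"))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select experiments co-activating a seed region
#'
#' The co-activation filter of meta-analytic connectivity modelling: keeps
#' the experiments reporting at least one focus whose nearest voxel lies
#' inside the seed mask. Experiment order is preserved.
#'
#' @param db a [foci_db].
#' @param seed a [stat_volume] of kind `"MASK"`.
#' @return The sub-database ([foci_db]); empty selections are returned with
#'   a warning.
#' @export
select_by_seed <- function(db, seed) {
  stopifnot(inherits(db, "foci_db"), inherits(seed, "stat_volume"))
  if (seed$kind != "MASK") stop("seed must be a MASK volume")
  grid <- seed$grid
  in_seed <- array(FALSE, grid$shape)
  in_seed[grid$mask_idx[seed$values > 0]] <- TRUE
  keep <- vapply(db$experiments, function(e) {
    vox <- mm_to_voxel(e$foci, grid)
    lin <- voxel_to_linear(vox, grid$shape)
    any(!is.na(lin) & in_seed[ifelse(is.na(lin), 1L, lin)])
  }, logical(1))
  if (!any(keep)) warning("no experiments report a focus inside the seed")
  foci_db(db$experiments[keep])
}

#' Pool two databases and randomly split into the original group sizes
#'
#' The relabelling step of the permutation difference test: experiments
#' from both inputs are pooled (experiments present in both contribute one
#' token per membership) and randomly partitioned into two groups of sizes
#' `length(dbA)` and `length(dbB)`.
#'
#' @param dbA,dbB [foci_db] objects.
#' @param rng_seed integer seed making the partition reproducible.
#' @return A list with elements `x` and `y` ([foci_db] objects).
#' @export
pool_and_split <- function(dbA, dbB, rng_seed) {
  stopifnot(inherits(dbA, "foci_db"), inherits(dbB, "foci_db"))
  pool <- c(dbA$experiments, dbB$experiments)
  nA <- length(dbA$experiments)
  seed_rng(rng_seed)
  pick <- sample.int(length(pool), nA)
  x <- pool[pick]
  y <- pool[-pick]
  list(x = foci_db(dedup_ids(x)), y = foci_db(dedup_ids(y)))
}

# Duplicate-token ids (same experiment drawn into one group twice through
# both memberships) are suffixed so the db invariant holds.
dedup_ids <- function(exps) {
  ids <- vapply(exps, function(e) e$id, character(1))
  dup <- duplicated(ids)
  if (any(dup)) {
    for (i in which(dup)) exps[[i]]$id <- paste0(exps[[i]]$id, "::dup", i)
  }
  exps
}

# Scoped RNG seeding: sets the seed without clobbering the caller's stream.
seed_rng <- function(seed) {
  if (!is.null(seed)) {
    seed <- as.integer(seed %% .Machine$integer.max)
    set.seed(seed)
  }
  invisible(NULL)
}
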