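#' Pedigree table
#'
#' A pedigree is a data frame with columns \code{id}, \code{mother},
#' \code{father} (NA = unknown), \code{selected} (logical: cultivars,
#' breeding selections and parents, as opposed to unselected seedlings).
#' Parents referenced but not listed are added as founder rows. The
#' structure must be acyclic (no individual is its own ancestor).
#'
#' @param id character vector of individual ids (nonempty, unique).
#' @param mother,father character vectors of parent ids (NA or ""
#'   = unknown).
#' @param selected logical vector (default all FALSE).
#' @return a data frame of class \code{pedigree}.
#' @export
pedigree <- function(id, mother = NA, father = NA, selected = FALSE) {
  n <- length(id)
  id <- as.character(id)
  if (any(is.na(id) | id == "")) stop("individual ids must be nonempty")
  if (anyDuplicated(id))
    stop("duplicated individual ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  clean <- function(x) { x <- as.character(rep_len(x, n)); x[x == ""] <- NA; x }
  ped <- data.frame(id = id, mother = clean(mother), father = clean(father),
                    selected = rep_len(as.logical(selected), n),
                    stringsAsFactors = FALSE)
  extra <- setdiff(c(ped$mother, ped$father), c(ped$id, NA))
  if (length(extra)) {
    ped <- rbind(data.frame(id = extra, mother = NA_character_,
                            father = NA_character_, selected = TRUE,
                            stringsAsFactors = FALSE), ped)
  }
  check_pedigree_acyclic(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

check_pedigree_acyclic <- function(ped) {
  # Kahn-style peel: repeatedly remove individuals all of whose parents
  # are already removed; leftovers form cycles.
  known <- ped$id
  parent_idx <- cbind(match(ped$mother, known), match(ped$father, known))
  done <- rep(FALSE, nrow(ped))
  repeat {
    ready <- !done &
      (is.na(parent_idx[, 1]) | done[parent_idx[, 1]]) &
      (is.na(parent_idx[, 2]) | done[parent_idx[, 2]])
    if (!any(ready)) break
    done[ready] <- TRUE
  }
  if (!all(done))
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[!done], collapse = ", "))
  invisible(TRUE)
}

#' Read / write a pedigree CSV
#'
#' Columns: individual, mother, father, selected (0/1); empty parent
#' fields mean unknown.
#' @param path file path.
#' @return \code{read_pedigree}: a \code{pedigree}.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  pedigree(df$individual, df$mother, df$father,
           selected = df$selected %in% c("1", "TRUE", "true"))
}

#' @rdname read_pedigree
#' @param ped a \code{pedigree}.
#' @export
write_pedigree <- function(ped, path) {
  df <- data.frame(individual = ped$id,
                   mother = ifelse(is.na(ped$mother), "", ped$mother),
                   father = ifelse(is.na(ped$father), "", ped$father),
                   selected = as.integer(ped$selected))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize a pedigree to the both-parents-or-none convention
#'
#' Individuals recorded with a single known parent gain a placeholder
#' parent so that downstream consistency checking sees either two parents
#' or none. Placeholders are named with the conventional prefixes
#' \code{M_} (unknown mother), \code{F_} (unknown father) or \code{UP_}
#' (role unspecified) followed by the child id, so each child gets its
#' own placeholder; a shared dummy parent would fabricate false full-sib
#' relationships. Placeholder individuals carry no genotype row and are
#' treated downstream as ungenotyped founders. The operation is
#' idempotent.
#'
#' @param ped a \code{pedigree}.
#' @param role_known if FALSE, the placeholder for a missing parent of
#'   unspecified role is prefixed \code{UP_} instead of \code{M_}/\code{F_}.
#' @return normalized \code{pedigree}.
#' @export
normalize_pedigree <- function(ped, role_known = TRUE) {
  need_m <- is.na(ped$mother) & !is.na(ped$father)
  need_f <- !is.na(ped$mother) & is.na(ped$father)
  if (!any(need_m | need_f)) return(ped)
  ped$mother[need_m] <- paste0(if (role_known) "M_" else "UP_", ped$id[need_m])
  ped$father[need_f] <- paste0(if (role_known) "F_" else "UP_", ped$id[need_f])
  new <- setdiff(c(ped$mother[need_m], ped$father[need_f]), ped$id)
  if (length(new))
    ped <- rbind(ped, data.frame(id = new, mother = NA_character_,
                                 father = NA_character_, selected = FALSE,
                                 stringsAsFactors = FALSE))
  class(ped) <- c("pedigree", "data.frame")
  check_pedigree_acyclic(ped)
  ped
}

#' Is an id a placeholder parent?
#' @param id character vector of ids.
#' @return logical vector.
#' @export
is_placeholder <- function(id) grepl("^(M_|F_|UP_)", id)

#' Nuclear families of a pedigree
#'
#' @param ped a normalized \code{pedigree}.
#' @return data frame with one row per (mother, father) pair plus a list
#'   column \code{children} of child id vectors.
#' @export
nuclear_families <- function(ped) {
  has <- !is.na(ped$mother) & !is.na(ped$father)
  if (!any(has))
    return(data.frame(mother = character(), father = character(),
                      children = I(list())))
  key <- paste(ped$mother[has], ped$father[has], sep = "\r")
  sp <- split(ped$id[has], key)
  mf <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  data.frame(mother = mf[, 1], father = mf[, 2], children = I(unname(sp)),
             stringsAsFactors = FALSE)
}

#' Generation number (founders = 0)
#' @param ped a \code{pedigree}.
#' @return named integer vector of generation indices.
#' @export
pedigree_generation <- function(ped) {
  gen <- stats::setNames(rep(NA_integer_, nrow(ped)), ped$id)
  mi <- match(ped$mother, ped$id); fi <- match(ped$father, ped$id)
  repeat {
    ready <- is.na(gen) &
      (is.na(mi) | !is.na(gen[mi])) & (is.na(fi) | !is.na(gen[fi]))
    if (!any(ready)) break
    g <- pmax(ifelse(is.na(mi[ready]), -1L, gen[mi[ready]]),
              ifelse(is.na(fi[ready]), -1L, gen[fi[ready]])) + 1L
    gen[ready] <- g
  }
  gen
}
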