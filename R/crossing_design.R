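#' Assemble and validate a line-by-tester crossing plan
#'
#' A crossing plan pairs candidate inbred lines with single-cross testers
#' from the opposite heterotic group. GCA effects are only jointly estimable
#' when the bipartite line-tester graph is connected, so connectivity is
#' enforced as a hard invariant.
#'
#' @param lines Data frame with columns `line_id` and `heterotic_group`
#'   (`"A"` or `"B"`); an optional `pedigree` column is carried along.
#' @param testers Data frame with columns `tester_id` and `heterotic_group`.
#' @param crosses Data frame with columns `line_id` and `tester_id`, the
#'   realised testcrosses.
#' @param check_groups If `TRUE` (default), every cross must pair a line with
#'   a tester of the opposite heterotic group. Set to `FALSE` for plans
#'   reconstructed from phenotype records where group membership is unknown.
#' @return An object of class `crossing_plan`.
#' @seealso [build_crossing_plan()] to generate the crosses from a rule.
#' @export
crossing_plan <- function(lines, testers, crosses, check_groups = TRUE) {
  lines <- as_tibble(lines)
  testers <- as_tibble(testers)
  crosses <- as_tibble(crosses)
  stopifnot(all(c("line_id", "heterotic_group") %in% names(lines)),
            all(c("tester_id", "heterotic_group") %in% names(testers)),
            all(c("line_id", "tester_id") %in% names(crosses)))
  if (anyDuplicated(lines$line_id)) abort("line_id values must be unique.")
  if (anyDuplicated(testers$tester_id)) abort("tester_id values must be unique.")
  if (anyDuplicated(crosses[c("line_id", "tester_id")])) {
    abort("Duplicated line x tester pairs in `crosses`.")
  }
  if (check_groups) {
    ok_grp <- c("A", "B")
    if (!all(lines$heterotic_group %in% ok_grp) ||
        !all(testers$heterotic_group %in% ok_grp)) {
      abort('heterotic_group must be "A" or "B".')
    }
  }
  unknown_l <- setdiff(crosses$line_id, lines$line_id)
  unknown_t <- setdiff(crosses$tester_id, testers$tester_id)
  if (length(unknown_l) || length(unknown_t)) {
    abort("`crosses` refers to unknown lines or testers.")
  }
  if (nrow(lines) > 0) {
    uncrossed <- setdiff(lines$line_id, crosses$line_id)
    if (length(uncrossed)) {
      abort(paste0("Line(s) with no cross: ",
                   paste(head(uncrossed, 5), collapse = ", ")))
    }
  }
  if (check_groups && nrow(crosses) > 0) {
    lg <- setNames(lines$heterotic_group, lines$line_id)
    tg <- setNames(testers$heterotic_group, testers$tester_id)
    same <- lg[crosses$line_id] == tg[crosses$tester_id]
    if (any(same)) {
      abort(sprintf(
        "Design error: %d cross(es) pair a line with a same-group tester (e.g. %s x %s).",
        sum(same), crosses$line_id[same][1], crosses$tester_id[same][1]
      ))
    }
  }
  plan <- structure(list(lines = lines, testers = testers, crosses = crosses),
                    class = "crossing_plan")
  plan$n_components <- plan_components(plan)
  plan
}

#' Build a crossing plan by crossing each line to opposite-group testers
#'
#' Each line is crossed to exactly `testers_per_line` testers of the opposite
#' heterotic group. When more opposite-group testers are available than
#' needed, assignment is deterministic by sorted tester label so the plan is
#' reproducible.
#'
#' @inheritParams crossing_plan
#' @param testers_per_line Number of testers per line (default 3).
#' @return A `crossing_plan` with `nrow(lines) * testers_per_line` crosses.
#' @examples
#' lines <- tibble::tibble(
#'   line_id = sprintf("L%03d", 1:10),
#'   heterotic_group = rep(c("A", "B"), each = 5)
#' )
#' testers <- tibble::tibble(
#'   tester_id = paste0("T", 1:6),
#'   heterotic_group = rep(c("A", "B"), each = 3)
#' )
#' plan <- build_crossing_plan(lines, testers, testers_per_line = 3)
#' design_summary(plan)$n_crosses # 30
#' @export
build_crossing_plan <- function(lines, testers, testers_per_line = 3L) {
  lines <- as_tibble(lines)
  testers <- as_tibble(testers)
  testers_per_line <- assert_count(testers_per_line, "testers_per_line")
  for (grp in unique(lines$heterotic_group)) {
    opp <- testers$tester_id[testers$heterotic_group != grp]
    if (length(opp) < testers_per_line) {
      abort(sprintf(
        "Design error: group %s lines need %d opposite-group testers but only %d are available.",
        grp, testers_per_line, length(opp)
      ))
    }
  }
  crosses <- purrr::map_dfr(seq_len(nrow(lines)), function(i) {
    opp <- sort(testers$tester_id[testers$heterotic_group !=
                                    lines$heterotic_group[i]])
    tibble(line_id = lines$line_id[i], tester_id = opp[seq_len(testers_per_line)])
  })
  crossing_plan(lines, testers, crosses)
}

crosses_graph <- function(line_id, tester_id) {
  edges <- rbind(paste0("L.", line_id), paste0("T.", tester_id))
  igraph::make_graph(as.vector(edges), directed = FALSE)
}

plan_components <- function(plan) {
  if (nrow(plan$crosses) == 0L) return(0L)
  igraph::components(crosses_graph(plan$crosses$line_id,
                                   plan$crosses$tester_id))$no
}

#' Is the line-tester graph of a plan connected?
#'
#' A two-group plan in which every line meets only opposite-group testers
#' splits into one component per heterotic group; GCA effects are then
#' estimable within each component and are centred per component by
#' [estimate_gca_sca()]. Use this check when fully connected GCA contrasts
#' are required.
#'
#' @param plan A `crossing_plan`.
#' @return `TRUE` if the bipartite line-tester graph has a single connected
#'   component.
#' @export
plan_is_connected <- function(plan) {
  stopifnot(inherits(plan, "crossing_plan"))
  plan_components(plan) <= 1L
}

#' Summarise a crossing plan
#'
#' @param plan A `crossing_plan`.
#' @return A list with per-group line counts, per-tester cross counts and the
#'   total number of crosses.
#' @export
design_summary <- function(plan) {
  stopifnot(inherits(plan, "crossing_plan"))
  list(
    lines_per_group = dplyr::count(plan$lines, .data$heterotic_group,
                                   name = "n_lines"),
    crosses_per_tester = dplyr::count(plan$crosses, .data$tester_id,
                                      name = "n_crosses"),
    n_lines = nrow(plan$lines),
    n_testers = nrow(plan$testers),
    n_crosses = nrow(plan$crosses),
    n_components = plan$n_components %||% plan_components(plan)
  )
}

#' @export
print.crossing_plan <- function(x, ...) {
  s <- design_summary(x)
  cat(sprintf("<crossing_plan> %d lines x %d testers, %d realised crosses\n",
              s$n_lines, s$n_testers, s$n_crosses))
  invisible(x)
}

#' Read a crossing plan from CSV files
#'
#' @param lines_path CSV with columns `line_id`, `heterotic_group`.
#' @param testers_path CSV with columns `tester_id`, `heterotic_group`.
#' @param crosses_path Optional CSV with columns `line_id`, `tester_id`; when
#'   absent the plan is generated with [build_crossing_plan()].
#' @param testers_per_line Used only when `crosses_path` is absent.
#' @return A `crossing_plan`.
#' @export
read_crossing_plan <- function(lines_path, testers_path, crosses_path = NULL,
                               testers_per_line = 3L) {
  rd <- function(p) readr::read_csv(p, na = c("NA", ""), show_col_types = FALSE,
                                    progress = FALSE)
  lines <- rd(lines_path)
  testers <- rd(testers_path)
  if (is.null(crosses_path)) {
    build_crossing_plan(lines, testers, testers_per_line)
  } else {
    crossing_plan(lines, testers, rd(crosses_path))
  }
}

# reconstruct a plan (without group information) from plot records
plan_from_records <- function(data) {
  tc <- dplyr::filter(data, .data$entry_kind == "testcross")
  crosses <- dplyr::distinct(tc, .data$line_id, .data$tester_id)
  crossing_plan(
    lines = tibble(line_id = unique(crosses$line_id),
                   heterotic_group = NA_character_),
    testers = tibble(tester_id = unique(crosses$tester_id),
                     heterotic_group = NA_character_),
    crosses = crosses,
    check_groups = FALSE
  )
}
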