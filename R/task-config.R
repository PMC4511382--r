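## Task configuration: type inventories, label-and-feature generalisations,
## instance-generation generalisations, and solver options.
##
## Config file grammar (plain text, '#' starts a comment):
##   section headers on their own line: GOLD, PREDICTION, TRIGGERS, ROLES,
##   LABEL_GENERALISATIONS, INSTANCE_RULES, OPTIONS
##   GOLD/PREDICTION/TRIGGERS/ROLES: one type or role name per line
##   LABEL_GENERALISATIONS:  Name -> Group   (pseudo-names @events and
##     @entities generalise any event/entity type in argument position)
##   INSTANCE_RULES: comma-separated sets of event types that share their
##     observed event structures at prediction time
##   OPTIONS: key = value

defaultTaskOptions <- function() {
  list(C = 1, hashBits = 20L, mode = "none", seed = 1L,
       charNgram = c(2L, 4L), wordNgram = c(1L, 3L),
       clip = c(1e-3, 1e3), pairCap = 10L)
}

#' Construct a TaskConfig
#'
#' @param goldTypes,predictionTypes,triggerTypes,roleTypes character type
#'   inventories (see [TaskConfig-class]).
#' @param labelGen named character vector of generalisation rules.
#' @param instanceRules list of character vectors of event types sharing
#'   structures.
#' @param options list merged over the defaults (\code{C = 1},
#'   \code{hashBits = 20}, \code{mode = "none"}, \code{seed = 1}, n-gram
#'   orders, density-ratio clipping bounds, argument-pair cap).
#' @return a validated [TaskConfig-class].
#' @export
taskConfig <- function(goldTypes = character(), predictionTypes = character(),
                       triggerTypes = character(), roleTypes = character(),
                       labelGen = character(), instanceRules = list(),
                       options = list()) {
  opts <- modifyList(defaultTaskOptions(), options)
  opts$hashBits <- as.integer(opts$hashBits)
  opts$seed <- as.integer(opts$seed)
  methods::new("TaskConfig", goldTypes = unique(goldTypes),
               predictionTypes = unique(predictionTypes),
               triggerTypes = unique(triggerTypes),
               roleTypes = unique(roleTypes), labelGen = labelGen,
               instanceRules = instanceRules, options = opts)
}

#' Look up a configuration option
#'
#' @param cfg a [TaskConfig-class].
#' @param name option name.
#' @return the option value (defaults applied).
#' @export
taskOption <- function(cfg, name) {
  (modifyList(defaultTaskOptions(), cfg@options))[[name]]
}

#' Parse a task configuration file
#'
#' @param src a file path or the configuration text.
#' @return a validated [TaskConfig-class].
#' @export
parseTaskConfig <- function(src) {
  lines <- asLines(src)
  lines <- sub("#.*$", "", lines)
  sections <- c("GOLD", "PREDICTION", "TRIGGERS", "ROLES",
                "LABEL_GENERALISATIONS", "INSTANCE_RULES", "OPTIONS")
  seen <- character()
  current <- NULL
  acc <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (ln %in% sections) {
      if (ln %in% seen)
        stopf("parse error at config line %d: duplicate section %s", i, ln)
      seen <- c(seen, ln)
      current <- ln
      acc[[current]] <- character()
      next
    }
    if (is.null(current))
      stopf("parse error at config line %d: content before any section header", i)
    ## all-caps underscore names of length >= 4 are reserved for headers
    if (grepl("^[A-Z][A-Z_]{3,}$", ln) && !(ln %in% sections))
      stopf("parse error at config line %d: unknown section %s", i, ln)
    acc[[current]] <- c(acc[[current]], ln)
  }
  labelGen <- character()
  for (ln in acc[["LABEL_GENERALISATIONS"]] %||% character()) {
    m <- regmatches(ln, regexec("^(\\S+)\\s*->\\s*(\\S+)$", ln))[[1]]
    if (length(m) != 3L)
      stopf("parse error: bad generalisation rule '%s' (expected 'Name -> Group')", ln)
    labelGen[m[[2]]] <- m[[3]]
  }
  rules <- lapply(acc[["INSTANCE_RULES"]] %||% character(), function(ln)
    trimws(strsplit(ln, ",", fixed = TRUE)[[1]]))
  opts <- list()
  for (ln in acc[["OPTIONS"]] %||% character()) {
    m <- regmatches(ln, regexec("^(\\w+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stopf("parse error: bad option line '%s' (expected 'key = value')", ln)
    key <- m[[2]]; val <- trimws(m[[3]])
    opts[[key]] <- if (key %in% c("mode")) val
      else if (grepl("[, ]", val)) as.numeric(trimws(strsplit(val, "[, ]+")[[1]]))
      else if (!is.na(suppressWarnings(as.numeric(val)))) as.numeric(val)
      else val
  }
  cfg <- taskConfig(goldTypes = acc[["GOLD"]] %||% character(),
                    predictionTypes = acc[["PREDICTION"]] %||% character(),
                    triggerTypes = acc[["TRIGGERS"]] %||% character(),
                    roleTypes = acc[["ROLES"]] %||% character(),
                    labelGen = labelGen, instanceRules = rules,
                    options = opts)
  cfg
}

#' Serialise a TaskConfig to config-file text
#'
#' @param cfg a [TaskConfig-class].
#' @return a single character string re-parseable by [parseTaskConfig()].
#' @export
writeTaskConfig <- function(cfg) {
  opts <- modifyList(defaultTaskOptions(), cfg@options)
  fmt <- function(v) paste(v, collapse = ", ")
  out <- c("GOLD", cfg@goldTypes, "", "PREDICTION", cfg@predictionTypes, "",
           "TRIGGERS", cfg@triggerTypes, "", "ROLES", cfg@roleTypes, "")
  if (length(cfg@labelGen))
    out <- c(out, "LABEL_GENERALISATIONS",
             paste(names(cfg@labelGen), "->", cfg@labelGen), "")
  if (length(cfg@instanceRules))
    out <- c(out, "INSTANCE_RULES",
             vapply(cfg@instanceRules, fmt, character(1)), "")
  out <- c(out, "OPTIONS",
           vapply(names(opts), function(k) paste(k, "=", fmt(opts[[k]])),
                  character(1)))
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Entity types of a configuration
#'
#' Entities are the annotation types that are given or predicted but never
#' anchor an event: \code{(GOLD union PREDICTION) minus TRIGGERS}.
#'
#' @param cfg a [TaskConfig-class].
#' @return character vector of entity type names.
#' @export
entityTypes <- function(cfg) {
  setdiff(union(cfg@goldTypes, cfg@predictionTypes), cfg@triggerTypes)
}

#' Derive a TaskConfig from an annotated corpus
#'
#' Builds the minimal configuration for a corpus: trigger types are the
#' types observed as event triggers, roles are the observed role names,
#' GOLD is the caller-identified .a1 side, PREDICTION is every other
#' observed annotation type. No generalisations are emitted.
#'
#' @param docs list of gold-annotated [StandoffDocument-class].
#' @param a1Types character vector naming the types that came from .a1
#'   files; defaults to the observed types never used as an event trigger.
#' @param options list of option overrides for the new config.
#' @return a [TaskConfig-class].
#' @export
deriveConfigFromCorpus <- function(docs, a1Types = NULL, options = list()) {
  if (length(docs) == 0L) stopf("cannot derive a configuration from an empty corpus")
  allTypes <- character(); trigTypes <- character(); roles <- character()
  for (doc in docs) {
    allTypes <- union(allTypes, doc@textbounds$type)
    for (e in doc@events) {
      j <- match(e$trigger, doc@textbounds$id)
      if (!is.na(j)) trigTypes <- union(trigTypes, doc@textbounds$type[j])
      roles <- union(roles, e$args$role)
    }
  }
  allTypes <- sort(allTypes, method = "radix")
  trigTypes <- sort(trigTypes, method = "radix")
  if (is.null(a1Types)) a1Types <- setdiff(allTypes, trigTypes)
  taskConfig(goldTypes = sort(intersect(a1Types, allTypes), method = "radix"),
             predictionTypes = setdiff(allTypes, a1Types),
             triggerTypes = trigTypes,
             roleTypes = sort(roles, method = "radix"),
             options = options)
}

#' Generalise a type or role name under a configuration
#'
#' Applies the label-and-feature generalisation rules: explicit
#' \code{Name -> Group} mappings, the \code{@events}/\code{@entities}
#' catch-alls for argument-position types, and role de-numbering
#' (\code{Theme2 -> Theme}) everywhere except in event structure labels,
#' where the numbers carry the correspondence between roles and are
#' retained. Unmapped names are returned unchanged, making the operation
#' idempotent.
#'
#' @param cfg a [TaskConfig-class].
#' @param name a type or role name (vectorised).
#' @param context where the generalised name will be used: an event role
#'   label (\code{"argument_label"}), an event structure label
#'   (\code{"structure_label"}), or a feature key (\code{"feature"}).
#' @param position what the name is within the label: an argument type, a
#'   trigger type, or a role name. Trigger-type collapses (e.g. the
#'   regulation family) apply in trigger position; the event/entity
#'   catch-alls apply in argument position; de-numbering applies in role
#'   position.
#' @return character vector of generalised names.
#' @export
generalizeType <- function(cfg, name,
                           context = c("argument_label", "structure_label",
                                       "feature"),
                           position = c("argument", "trigger", "role")) {
  context <- match.arg(context)
  position <- match.arg(position)
  if (position == "role") {
    mapped <- ifelse(name %in% names(cfg@labelGen) & context != "structure_label",
                     unname(cfg@labelGen[name]), name)
    if (context != "structure_label") mapped <- deNumberRole(mapped)
    return(mapped)
  }
  out <- ifelse(name %in% names(cfg@labelGen), unname(cfg@labelGen[name]), name)
  if (position == "argument") {
    miss <- !(name %in% names(cfg@labelGen))
    if ("@events" %in% names(cfg@labelGen)) {
      hit <- miss & name %in% cfg@triggerTypes
      out[hit] <- cfg@labelGen[["@events"]]
    }
    if ("@entities" %in% names(cfg@labelGen)) {
      hit <- miss & name %in% entityTypes(cfg)
      out[hit] <- cfg@labelGen[["@entities"]]
    }
  }
  out
}

## ---- inventories -----------------------------------------------------------

roleLabelKey <- function(trigger, role, arg) paste0(trigger, ":", role, "-", arg)
structureKey <- function(trigger, roles, args) paste0(trigger, "|", slotKey(roles, args))

## Head token of a span: the token whose dependency head lies outside the
## span (if a parse is present), otherwise the rightmost covered token.
headTokenIndex <- function(doc, start, end) {
  tk <- doc@tokens
  inside <- which(tk$start < end & tk$end > start)
  if (length(inside) == 0L) return(NA_integer_)
  if (length(inside) == 1L) return(inside)
  ext <- inside[!(tk$head[inside] %in% inside)]
  if (length(ext)) ext[length(ext)] else inside[length(inside)]
}

eventTypeOf <- function(doc, targetId) {
  j <- match(targetId, doc@textbounds$id)
  if (!is.na(j)) return(doc@textbounds$type[j])
  for (e in doc@events) if (e$id == targetId) return(e$type)
  NA_character_
}

## Resolve an argument target to the textbound that anchors it (the target
## itself, or the trigger of the target event).
anchorTextbound <- function(doc, targetId) {
  if (targetId %in% doc@textbounds$id) return(targetId)
  for (e in doc@events) if (e$id == targetId) return(e$trigger)
  NA_character_
}

#' Collect label inventories and the head-word table from training data
#'
#' Enumerates, over a gold-annotated corpus, the generalised event role
#' labels (trigger type : role - argument type), the event structure labels
#' (trigger type with its full numbered role/argument-type multiset), and
#' the head-word table mapping surface/base/stem head forms to the
#' annotation types they anchor.
#'
#' @param docs list of gold-annotated [StandoffDocument-class].
#' @param cfg a [TaskConfig-class]; types observed outside its inventories
#'   raise a validation error.
#' @return list with elements \code{roleLabels} (data.frame: trigger, role,
#'   arg, key, crossSentence, expandedFrom), \code{structureLabels} (named
#'   list of trigger + slots records) and \code{headTable} (data.frame:
#'   form, type).
#' @export
collectInventories <- function(docs, cfg) {
  detectTypes <- union(cfg@predictionTypes, cfg@triggerTypes)
  roleRows <- list(); structs <- list(); headRows <- list()
  for (doc in docs) {
    tb <- doc@textbounds
    bad <- setdiff(tb$type, union(cfg@goldTypes, cfg@predictionTypes))
    if (length(bad))
      stopf("validation error: corpus uses type(s) outside the configuration: %s",
            paste(unique(bad), collapse = ", "))
    for (i in seq_len(nrow(tb))) {
      if (!(tb$type[i] %in% detectTypes)) next
      h <- headTokenIndex(doc, tb$start[i], tb$end[i])
      if (is.na(h)) next
      tk <- doc@tokens[h, ]
      headRows[[length(headRows) + 1L]] <-
        data.frame(form = unique(c(tk$surface, tk$base, tk$stem)),
                   type = tb$type[i], stringsAsFactors = FALSE)
    }
    for (e in doc@events) {
      evType <- e$type
      if (!(evType %in% cfg@triggerTypes))
        stopf("validation error: event type %s is not a configured trigger type",
              evType)
      trigGenA <- generalizeType(cfg, evType, "argument_label", "trigger")
      trigGenS <- generalizeType(cfg, evType, "structure_label", "trigger")
      trigTok <- headTokenIndex(doc, tb$start[match(e$trigger, tb$id)],
                                tb$end[match(e$trigger, tb$id)])
      argsA <- character(); argsS <- character()
      rolesA <- character(); rolesS <- character()
      cross <- logical()
      for (k in seq_len(nrow(e$args))) {
        tType <- eventTypeOf(doc, e$args$target[k])
        if (is.na(tType))
          stopf("validation error: %s references unknown target %s",
                e$id, e$args$target[k])
        rolesA[k] <- generalizeType(cfg, e$args$role[k], "argument_label", "role")
        rolesS[k] <- generalizeType(cfg, e$args$role[k], "structure_label", "role")
        argsA[k] <- generalizeType(cfg, tType, "argument_label", "argument")
        argsS[k] <- generalizeType(cfg, tType, "structure_label", "argument")
        anchor <- anchorTextbound(doc, e$args$target[k])
        aTok <- if (is.na(anchor)) NA_integer_
                else headTokenIndex(doc, tb$start[match(anchor, tb$id)],
                                    tb$end[match(anchor, tb$id)])
        cross[k] <- !is.na(trigTok) && !is.na(aTok) &&
          doc@tokens$sentence[trigTok] != doc@tokens$sentence[aTok]
      }
      for (k in seq_along(rolesA)) {
        roleRows[[length(roleRows) + 1L]] <-
          data.frame(trigger = trigGenA, role = rolesA[k], arg = argsA[k],
                     key = roleLabelKey(trigGenA, rolesA[k], argsA[k]),
                     crossSentence = cross[k], stringsAsFactors = FALSE)
      }
      sk <- structureKey(trigGenS, rolesS, argsS)
      if (is.null(structs[[sk]]))
        structs[[sk]] <- list(trigger = trigGenS,
                              slots = data.frame(role = rolesS, arg = argsS,
                                                 stringsAsFactors = FALSE),
                              key = sk, expandedFrom = NA_character_)
    }
  }
  roleLabels <- if (length(roleRows)) {
    df <- do.call(rbind, roleRows)
    agg <- aggregate(crossSentence ~ trigger + role + arg + key, data = df, FUN = any)
    agg <- agg[cOrder(agg$key), , drop = FALSE]
    agg$expandedFrom <- NA_character_
    rownames(agg) <- NULL
    agg
  } else data.frame(trigger = character(), role = character(),
                    arg = character(), key = character(),
                    crossSentence = logical(), expandedFrom = character(),
                    stringsAsFactors = FALSE)
  headTable <- if (length(headRows)) {
    ht <- unique(do.call(rbind, headRows))
    ht <- ht[cOrder(ht$form, ht$type), , drop = FALSE]
    rownames(ht) <- NULL
    ht
  } else data.frame(form = character(), type = character(),
                    stringsAsFactors = FALSE)
  if (length(structs))
    structs <- structs[sort(names(structs), method = "radix")]
  list(roleLabels = roleLabels, structureLabels = structs,
       headTable = headTable)
}

#' Expand event structures across instance-generation rules
#'
#' For every configured rule set, each structure observed for one member
#' event type is duplicated for every other member, so that prediction-time
#' candidate enumeration also covers structures never seen with a given
#' trigger type. The result always contains the input (monotone) and the
#' operation is idempotent. Expanded entries record their source label,
#' whose trained scorer they share.
#'
#' @param cfg a [TaskConfig-class].
#' @param inventory named list of structure records as produced by
#'   [collectInventories()].
#' @return the expanded named list of structure records.
#' @export
expandStructures <- function(cfg, inventory) {
  out <- inventory
  for (rule in cfg@instanceRules) {
    genMembers <- unique(generalizeType(cfg, rule, "structure_label", "trigger"))
    for (s in inventory) {
      if (!(s$trigger %in% genMembers)) next
      for (m in genMembers) {
        if (m == s$trigger) next
        nk <- structureKey(m, s$slots$role, s$slots$arg)
        if (is.null(out[[nk]]))
          out[[nk]] <- list(trigger = m, slots = s$slots, key = nk,
                            expandedFrom = if (is.na(s$expandedFrom)) s$key
                                           else s$expandedFrom)
      }
    }
  }
  if (length(out)) out <- out[sort(names(out), method = "radix")]
  out
}

## Role-label analogue of expandStructures, used at prediction time so that
## argument pairs for rule-sibling trigger types are enumerated too.
expandRoleLabels <- function(cfg, roleLabels) {
  out <- roleLabels
  for (rule in cfg@instanceRules) {
    genMembers <- unique(generalizeType(cfg, rule, "argument_label", "trigger"))
    sel <- roleLabels[roleLabels$trigger %in% genMembers, , drop = FALSE]
    for (m in genMembers) {
      add <- sel[sel$trigger != m, , drop = FALSE]
      if (nrow(add) == 0L) next
      add$expandedFrom <- ifelse(is.na(add$expandedFrom), add$key,
                                 add$expandedFrom)
      add$trigger <- m
      add$key <- roleLabelKey(m, add$role, add$arg)
      out <- rbind(out, add[!(add$key %in% out$key), , drop = FALSE])
    }
  }
  out <- out[cOrder(out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
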