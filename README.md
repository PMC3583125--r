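# dagflow

A pattern-based dataflow workflow engine for sequence-analysis pipelines,
written in R.

Bioinformatics analyses are naturally expressed as directed acyclic graphs
(DAGs): nodes are computational tools, edges carry data between named
ports. Plain DAG runners, however, lack the recurring *workflow patterns*
that real pipelines need — conditionals, loops, and parallel processing of
sequence collections. `dagflow` implements these patterns explicitly on a
data-availability-driven engine, together with importers for two foreign
workflow dialects and an optimizer that minimizes how often a foreign
engine must be invoked for delegated sub-workflows.

## The model

A workflow is a DAG `G = (V, E)` where each node fires when and only when
every in-port has received a token. Tokens carry a status:

* `DATA` — a payload (sequence text, tabular hits, ...); may be a nested
  *list* of tokens;
* `DUMMY` — a pure execution dependency, satisfied but never handed to a
  tool;
* `FAIL` — a pruned branch: a node receiving `FAIL` is skipped without
  spawning a process and passes `FAIL` downstream.

**Control patterns.** Sequence, synchronous merge and fork are structural
(ports + readiness). The *multi-choice switch* evaluates a user predicate
Ψ once and routes its input to exactly one branch, emitting `FAIL` on the
rest. *Iteration* is a do-while: a nested sub-workflow body runs at least
once, designated outputs overwrite inputs between passes, and a predicate
(or `max_iterations`) terminates the loop.

**Data patterns.** A port marked as a list expands a node into independent
task instances: `MAP` over one list of *n* items gives *n* instances;
`DOT` of lists of lengths *n ≤ m* gives the *n* index-wise pairs
`(a_i, b_i)` (trailing items ignored); `CROSS` gives all *n·m* pairs in
row-major order — one search node crossed over 11 query blocks and 3
databases fans out to 33 jobs. `select` returns one of two inputs by
predicate, `collect` concatenates inputs into a (possibly nested) list,
and `split_into_list` turns a multi-FASTA file into a list of records or
⌈N/k⌉ blocks of k records.

Every tool runs behind a generic wrapper that gates on tokens, expands
lists, renders a command template to an argv vector (or calls an
in-process stub), and reassembles outputs in input order regardless of
completion order. Static single-processor schedules are topological orders
with a lexicographic tie-break; with deterministic tools, outputs are
byte-identical for any worker count.

**Interoperability.** `wf_import()` translates a simplified XML processor
dialect (conditionals → switch nodes, nested workflows → composite nodes,
remote services → external nodes) and a simplified JSON step dialect into
the native JSON format; a service catalog can substitute remote calls with
equivalent local tools. `wf_find_external_subworkflows()` partitions the
remaining external nodes into *maximal external sub-workflows* — weakly
connected external-only sets whose condensation keeps the graph acyclic —
and `wf_encapsulate()` replaces each by one composite node, so the foreign
engine is invoked exactly once per component through a command-line
delegation contract (`body.json`, `inputs/<port>`, `outputs/<port>`).

## Worked example

The bundled metagenomics fixture re-expresses a read-classification
pipeline with the list pattern: length-filtered toy reads are split into
blocks of 10 records, crossed with a collected list of 3 toy databases,
searched with a deterministic k-mer stub, coverage-filtered per instance,
collected, and tallied by database label.

```r
library(dagflow)
g   <- build_case_study("metagenomics")
ins <- wf_case_inputs("metagenomics")   # 110 toy reads + 3 bundled toy DBs
res <- wf_run(g, ins, workers = 4)
res
#> <wf_result success: 2 outputs, 142 trace events, 68 invocations, 0 delegations>
cat(res$outputs$taxonomy$payload)
#> dbA	440
#> dbB	440
#> dbC	440
sum(res$trace$node_id == "search" & res$trace$event == "start" &
    !is.na(res$trace$instance))
#> [1] 33
wf_static_schedule(g)
#> [1] "dbs"      "qc"       "split"    "search"   "coverage" "gather"   "tax"
```

The 110 reads form ⌈110/10⌉ = 11 blocks; crossed with 3 databases the
single search node expands to 11 × 3 = 33 task instances, visible in the
run trace. The taxonomy output tallies hits per database label (110
surviving reads × 4 records per database). Swapping the stub for a real
search tool is a one-line `wf_tool()` registration with a command
template.

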