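#!/usr/bin/env python
"""Independent sentence-BLEU oracle.

Reads a tab-separated file with two columns (space-joined reference
tokens, space-joined candidate tokens) plus four weight values from the
command line, and prints one BLEU score per line.

This is a direct transcription of the clipped n-gram precision /
brevity penalty definitions and shares no code with the R
implementation it cross-checks.
"""
import sys
from collections import Counter
from math import exp, log


def ngrams(tokens, n):
    return Counter(tuple(tokens[i:i + n]) for i in range(len(tokens) - n + 1))


def modified_precision(reference, candidate, n):
    cand = ngrams(candidate, n)
    total = sum(cand.values())
    if total == 0:
        return 0.0
    ref = ngrams(reference, n)
    clipped = sum(min(c, ref.get(g, 0)) for g, c in cand.items())
    return clipped / total


def brevity_penalty(r, c):
    if c == 0:
        return 0.0
    if c >= r:
        return 1.0
    return exp(1.0 - r / c)


def sentence_bleu(reference, candidate, weights):
    bp = brevity_penalty(len(reference), len(candidate))
    if bp == 0.0:
        return 0.0
    acc = 0.0
    for n, w in enumerate(weights, start=1):
        if w <= 0:
            continue
        p = modified_precision(reference, candidate, n)
        if p == 0.0:
            return 0.0
        acc += w * log(p)
    return bp * exp(acc)


def main():
    path = sys.argv[1]
    weights = [float(x) for x in sys.argv[2:6]]
    with open(path, encoding="utf-8") as fh:
        for line in fh:
            parts = line.rstrip("\n").split("\t")
            ref = parts[0].split() if parts[0] else []
            cand = parts[1].split() if len(parts) > 1 and parts[1] else []
            print(repr(sentence_bleu(ref, cand, weights)))


if __name__ == "__main__":
    main()
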