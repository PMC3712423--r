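# Female path model: same structure without aggressiveness (not assayed),
# original path numbering retained.
6: exploration -> feed_own
7: exploration -> fledgling_no
8: exploration -> fledgling_mass
9: exploration -> lay_date
10: feed_own -> feed_partner
11: feed_own -> fledgling_no
12: feed_own -> fledgling_mass
13: feed_partner -> fledgling_no
14: feed_partner -> fledgling_mass
15: lay_date -> brood_size
16: brood_size -> feed_own
17: brood_size -> feed_partner
18: brood_size -> fledgling_no
19: brood_size -> fledgling_mass
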