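screen:
- 1680
- 1050
matrix_cells:
- row: 0
  col: 0
  x0: 90.0
  y0: 225.0
  x1: 280.0
  y1: 415.0
- row: 0
  col: 1
  x0: 290.0
  y0: 225.0
  x1: 480.0
  y1: 415.0
- row: 0
  col: 2
  x0: 490.0
  y0: 225.0
  x1: 680.0
  y1: 415.0
- row: 1
  col: 0
  x0: 90.0
  y0: 425.0
  x1: 280.0
  y1: 615.0
- row: 1
  col: 1
  x0: 290.0
  y0: 425.0
  x1: 480.0
  y1: 615.0
- row: 1
  col: 2
  x0: 490.0
  y0: 425.0
  x1: 680.0
  y1: 615.0
- row: 2
  col: 0
  x0: 90.0
  y0: 625.0
  x1: 280.0
  y1: 815.0
- row: 2
  col: 1
  x0: 290.0
  y0: 625.0
  x1: 480.0
  y1: 815.0
- row: 2
  col: 2
  x0: 490.0
  y0: 625.0
  x1: 680.0
  y1: 815.0
answer_choices:
- choice: 0
  x0: 900.0
  y0: 350.0
  x1: 1060.0
  y1: 510.0
- choice: 1
  x0: 1070.0
  y0: 350.0
  x1: 1230.0
  y1: 510.0
- choice: 2
  x0: 1240.0
  y0: 350.0
  x1: 1400.0
  y1: 510.0
- choice: 3
  x0: 1410.0
  y0: 350.0
  x1: 1570.0
  y1: 510.0
- choice: 4
  x0: 900.0
  y0: 520.0
  x1: 1060.0
  y1: 680.0
- choice: 5
  x0: 1070.0
  y0: 520.0
  x1: 1230.0
  y1: 680.0
- choice: 6
  x0: 1240.0
  y0: 520.0
  x1: 1400.0
  y1: 680.0
- choice: 7
  x0: 1410.0
  y0: 520.0
  x1: 1570.0
  y1: 680.0
item_keys:
- trial_id: P1
  correct_choice: 3.0
  is_practice: yes
- trial_id: P2
  correct_choice: 5.0
  is_practice: yes
- trial_id: P3
  correct_choice: 0.0
  is_practice: yes
- trial_id: T01
  correct_choice: 2.0
  is_practice: no
- trial_id: T02
  correct_choice: 7.0
  is_practice: no
- trial_id: T03
  correct_choice: 1.0
  is_practice: no
- trial_id: T04
  correct_choice: 4.0
  is_practice: no
- trial_id: T05
  correct_choice: 6.0
  is_practice: no
- trial_id: T06
  correct_choice: 0.0
  is_practice: no
- trial_id: T07
  correct_choice: 3.0
  is_practice: no
- trial_id: T08
  correct_choice: 5.0
  is_practice: no
- trial_id: T09
  correct_choice: 2.0
  is_practice: no
- trial_id: T10
  correct_choice: 1.0
  is_practice: no
- trial_id: T11
  correct_choice: 7.0
  is_practice: no
- trial_id: T12
  correct_choice: 6.0
  is_practice: no
- trial_id: T13
  correct_choice: 4.0
  is_practice: no
- trial_id: T14
  correct_choice: 2.0
  is_practice: no
- trial_id: T15
  correct_choice: 0.0
  is_practice: no
- trial_id: T16
  correct_choice: 5.0
  is_practice: no
- trial_id: T17
  correct_choice: 3.0
  is_practice: no
- trial_id: T18
  correct_choice: 1.0
  is_practice: no
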