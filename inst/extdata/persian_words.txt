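بیمارستان
پزشک
درمان
دارو
پرستار
بخش
اتاق
تخت
غذا
محیط
نظافت
رفتار
پرسنل
نوبت
هزینه
بیمه
آزمایش
جراحی
عمل
امید
زندگی
خانواده
دکتر
کادر
خدمت
کیفیت
برخورد
وقت
ساعت
روز
شب
هفته
ماه
سال
شهر
تهران
مرکز
درد
بیماری
سرطان
دستگاه
تجهیزات
امکانات
فضا
سالن
راهرو
آسانسور
پله
پنجره
دیوار
کف
سقف
ملافه
بالش
پتو
لباس
کفش
دست
صورت
چشم
قلب
خون
نمونه
جواب
نتیجه
پرونده
پذیرش
ترخیص
ویزیت
مشاوره
روحیه
انگیزه
تلاش
کمک
همراه
مراجعه
انتظار
صف
شلوغی
سکوت
صدا
هوا
تهویه
گرما
سرما
نور
چراغ
آب
نان
میوه
سوپ
چای
شیر
قاشق
بشقاب
لیوان
سینی
دستشویی
حمام
ملاقات
اجازه
قانون
مدیر
مسئول
کارمند
نگهبان
تلفن
پیام
فرم
کاغذ
خودکار
کتاب
مجله
تلویزیون
یخچال
پریز
کپسول
ویلچر
برانکارد
آمبولانس
اورژانس
داروخانه
آزمایشگاه
رادیولوژی
سونوگرافی
پانسمان
سرنگ
واکسن
پیرمرد
پرتو
متخصص
منشی
بوفه
پارکینگ
ورودی
خروجی
طبقه
پرده
میز
صندلی
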